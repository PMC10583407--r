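# shared fixtures and oracles, all built in code

# two-Gaussian table: class "a" (positive) at +mu, class "b" at -mu, unit SD
make_gaussian_table <- function(n_per_class = 30, d = 2, mu = 2, seed = 1) {
  withr::with_seed(seed, {
    vals <- rbind(
      matrix(rnorm(n_per_class * d, mean = mu), ncol = d),
      matrix(rnorm(n_per_class * d, mean = -mu), ncol = d)
    )
  })
  colnames(vals) <- paste0("v", seq_len(d))
  dat <- tibble::as_tibble(vals)
  dat$label <- rep(c("a", "b"), each = n_per_class)
  feature_table(dat, label_col = "label", positive_class = "a")
}

# fast training config for unit tests
quick_config <- function(max_epochs = 300L, ...) {
  analysis_config(max_epochs = max_epochs, ...)
}

# direct Bayes-rule posterior of a C-class Gaussian mixture; the oracle the
# log-linearized network must reproduce
gmm_bayes_posterior <- function(priors, means, covariances, x) {
  c_n <- nrow(priors)
  m_n <- ncol(priors)
  d <- dim(means)[3]
  dens <- matrix(0, c_n, m_n)
  for (cc in seq_len(c_n)) {
    for (mm in seq_len(m_n)) {
      mu <- as.numeric(means[cc, mm, ])
      sigma <- matrix(covariances[cc, mm, , ], nrow = d)
      quad <- drop(t(x - mu) %*% solve(sigma) %*% (x - mu))
      dens[cc, mm] <- priors[cc, mm] *
        exp(-0.5 * quad) / sqrt((2 * pi)^d * det(sigma))
    }
  }
  rowSums(dens) / sum(dens)
}

# random symmetric positive-definite matrix
random_spd <- function(d) {
  a <- matrix(rnorm(d * d), d, d)
  crossprod(a) + diag(d) * 0.5
}

# random mixture parameters for C classes, M components, dimension d
random_gmm <- function(c_n, m_n, d) {
  priors <- matrix(abs(rnorm(c_n * m_n)) + 0.1, c_n, m_n)
  priors <- priors / sum(priors)
  means <- array(rnorm(c_n * m_n * d), dim = c(c_n, m_n, d))
  covs <- array(0, dim = c(c_n, m_n, d, d))
  for (cc in seq_len(c_n)) for (mm in seq_len(m_n)) {
    covs[cc, mm, , ] <- random_spd(d)
  }
  list(priors = priors, means = means, covariances = covs)
}

# brute-force lasso solution for small p by sign-pattern enumeration:
# solves the KKT system for every sign pattern and keeps the consistent one
lasso_enumerate <- function(x_mat, y, lambda) {
  n <- nrow(x_mat)
  p <- ncol(x_mat)
  yc <- y - mean(y)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  best <- NULL
  for (r in seq_len(nrow(signs))) {
    s <- signs[r, ]
    active <- which(s != 0)
    beta <- rep(0, p)
    if (length(active) > 0) {
      g <- crossprod(x_mat[, active, drop = FALSE]) / n
      rhs <- crossprod(x_mat[, active, drop = FALSE], yc) / n - lambda * s[active]
      sol <- tryCatch(solve(g, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      beta[active] <- sol
      if (any(sign(beta[active]) != s[active])) next
    }
    res <- yc - x_mat %*% beta
    grad <- abs(crossprod(x_mat, res)) / n
    if (length(active) < p && any(grad[setdiff(seq_len(p), active)] > lambda + 1e-9)) next
    best <- beta
    break
  }
  best
}

# exhaustive two-sided Fisher p for a 2x2 table with fixed margins
fisher_enumerate <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(ai) {
    stats::dhyper(ai, c1, n - c1, r1)
  }, numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
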