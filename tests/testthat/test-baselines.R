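test_that("partial KLI is zero for ignored indices and matches hand substitution", {
  # model that only looks at v1: mixture parameters flat in v2
  g <- list(priors = matrix(0.5, 2, 1),
            means = array(c(-1, 1, 0, 0), dim = c(2, 1, 2)),
            covariances = array(rep(diag(2), each = 2), dim = c(2, 1, 2, 2)))
  model <- log_linearize_gmm(g$priors, g$means, g$covariances)
  model$index_names <- c("v1", "v2")
  dat <- tibble::tibble(v1 = c(-0.9, 0.2, 1.4), v2 = c(2, -1, 0.5),
                        label = c("a", "b", "b"))
  tab <- feature_table(dat, positive_class = "a")

  expect_equal(partial_kli(model, tab, "v2"), 0)

  # hand evaluation for v1: substitute the (standardized) training mean 0
  ce_of <- function(vals) {
    p <- t(apply(vals, 1, function(x)
      gmm_bayes_posterior(g$priors, g$means, g$covariances, x)))
    t_mat <- cbind(ft_labels(tab) == 1L, ft_labels(tab) == 2L)
    -sum(log(pmax(p[t_mat], 1e-12)))
  }
  vals <- ft_values(tab)
  subbed <- vals
  subbed[, 1] <- 0
  expect_equal(partial_kli(model, tab, "v1"), ce_of(subbed) - ce_of(vals),
               tolerance = 1e-9)
  expect_error(partial_kli(model, tab, "nope"), "Unknown")
})

test_that("a model trained to ignore a duplicated column gives it near-zero KLI", {
  withr::with_seed(14, {
    x <- rnorm(60)
    dat <- tibble::tibble(v1 = x + rep(c(2, -2), each = 30),
                          label = rep(c("a", "b"), each = 30))
    dat$v2 <- dat$v1  # exact duplicate carries no extra information
  })
  tab <- standardize(feature_table(dat, positive_class = "a"))
  fit <- train_llgmn(tab, quick_config(seed = 3))
  k1 <- partial_kli(fit, tab, "v1")
  k2 <- partial_kli(fit, tab, "v2")
  # both carry the same signal; neither dominates and each substitution is
  # partly compensated by its twin
  expect_lt(abs(k1 - k2), 0.2 * max(abs(k1), abs(k2), 1))
})

test_that("stepwise elimination removes noise first and has a full trace", {
  noise_first <- 0L
  for (s in 1:10) {
    withr::with_seed(200 + s, {
      dat <- tibble::tibble(signal = rnorm(60) + rep(c(1.5, -1.5), each = 30),
                            noise = rnorm(60),
                            label = rep(c("a", "b"), each = 30))
    })
    tab <- feature_table(dat, positive_class = "a")
    st <- stepwise_kli_selection(tab, quick_config(n_folds = 3, seed = s))
    expect_equal(nrow(st$trace), 2L)
    expect_equal(sum(!is.na(st$trace$removed)), 1L)  # P - 1 removals
    noise_first <- noise_first + (st$trace$removed[1] == "noise")
  }
  expect_gte(noise_first, 8L)
})

test_that("stepwise traces are reproducible under a fixed seed", {
  sig <- generate_sparse_signal(n = 40, p = 5, k = 2, d = 2, seed = 31)
  cfg <- quick_config(n_folds = 3, seed = 12)
  s1 <- stepwise_kli_selection(sig$table, cfg)
  s2 <- stepwise_kli_selection(sig$table, cfg)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$selected, s2$selected)
  expect_equal(nrow(s1$trace), 5L)
  expect_equal(sum(!is.na(s1$trace$removed)), 4L)
})

test_that("AUC-drop importance is reproducible and forgives redundant columns", {
  withr::with_seed(41, {
    base_sig <- rnorm(80) + rep(c(1.5, -1.5), each = 40)
    dat <- tibble::tibble(s1 = base_sig,
                          s2 = base_sig + rnorm(80, sd = 0.05),  # near-duplicate
                          n1 = rnorm(80),
                          label = rep(c("a", "b"), each = 40))
  })
  tab <- feature_table(dat, positive_class = "a")
  cfg <- quick_config(n_folds = 4, seed = 3)
  drop1 <- auc_drop_importance(tab, cfg)
  drop2 <- auc_drop_importance(tab, cfg)
  expect_identical(drop1, drop2)
  # each redundant twin is covered by the other on deletion
  expect_lt(abs(drop1$auc_reduction_pct[drop1$index == "s1"]), 5)
  expect_lt(abs(drop1$auc_reduction_pct[drop1$index == "s2"]), 5)
  # pure noise deletion changes little (negative drops are legal)
  expect_lt(drop1$auc_reduction_pct[drop1$index == "n1"], 5)
  expect_error(auc_drop_importance(sparsellgmn:::ft_subset_indices(tab, "s1"), cfg),
               "two indices")
})

test_that("lasso coordinate descent hits the closed-form cases", {
  # above the all-zero threshold every coefficient vanishes
  withr::with_seed(5, {
    n <- 40
    dat <- tibble::tibble(v1 = rnorm(n), v2 = rnorm(n),
                          label = rep(c("a", "b"), n / 2))
  })
  tab <- standardize(feature_table(dat, positive_class = "a"))
  x_mat <- ft_values(tab)
  y <- as.numeric(ft_labels(tab) == 1L)
  lmax <- max(abs(crossprod(x_mat, y - mean(y)))) / n
  fit_zero <- lasso_fit(tab, lmax * 1.001)
  expect_true(all(fit_zero$coefficients == 0))
  expect_equal(fit_zero$intercept, mean(y))

  # lambda = 0 on orthonormalized predictors reproduces least squares
  q <- qr.Q(qr(cbind(x_mat[, 1] - mean(x_mat[, 1]), x_mat[, 2] - mean(x_mat[, 2]))))
  colnames(q) <- c("q1", "q2")
  tabq <- feature_table(dplyr::mutate(tibble::as_tibble(q), label = dat$label),
                        positive_class = "a")
  tabq <- apply_standardization(
    tabq, tibble::tibble(index = c("q1", "q2"), mean = 0, sd = 1))
  fit_ols <- lasso_fit(tabq, 0)
  beta_ols <- drop(crossprod(q, y - mean(y)))  # q is orthonormal
  expect_equal(unname(fit_ols$coefficients), unname(beta_ols), tolerance = 1e-7)

  # univariate soft threshold: x'y/N = 0.5, lambda = 0.2 -> beta = 0.3
  # (x scaled so that x'x/N = 1, carried by the stored parameters)
  n1 <- 20
  withr::with_seed(8, x1 <- scale(rnorm(n1))[, 1] * sqrt(n1 / (n1 - 1)))
  y1 <- 0.5 * x1  # then x1' y1 / n = 0.5 exactly since x1'x1 = n
  dat1 <- tibble::tibble(v = x1, label = rep(c("a", "b"), n1 / 2))
  tab1 <- feature_table(dat1, positive_class = "a")
  tab1 <- apply_standardization(tab1, tibble::tibble(index = "v", mean = 0, sd = 1))
  fit1 <- sparsellgmn:::lasso_cd(matrix(x1, ncol = 1), y1, 0.2)
  expect_equal(unname(fit1$beta), 0.3, tolerance = 1e-8)
})

test_that("coordinate descent satisfies the KKT conditions and matches enumeration", {
  withr::with_seed(19, {
    x_mat <- scale(matrix(rnorm(15), 5, 3))
    colnames(x_mat) <- c("v1", "v2", "v3")
    y <- c(1, 0, 1, 0, 1)
  })
  lambda <- 0.15
  cd <- sparsellgmn:::lasso_cd(x_mat, y, lambda)
  oracle <- lasso_enumerate(x_mat, y, lambda)
  expect_equal(unname(cd$beta), oracle, tolerance = 1e-6)

  n <- nrow(x_mat)
  r <- y - cd$intercept - drop(x_mat %*% cd$beta)
  grad <- drop(crossprod(x_mat, r)) / n
  active <- cd$beta != 0
  expect_true(all(abs(grad[active] - lambda * sign(cd$beta[active])) < 1e-6))
  expect_true(all(abs(grad[!active]) <= lambda + 1e-6))
})

test_that("lasso agrees with an independent penalized-regression solver", {
  skip_if_not_installed("glmnet")
  withr::with_seed(23, {
    n <- 50
    x_mat <- scale(matrix(rnorm(n * 4), n, 4)) * sqrt(n / (n - 1))
    colnames(x_mat) <- paste0("v", 1:4)
    y <- as.numeric(x_mat[, 1] * 0.8 - x_mat[, 3] * 0.4 + rnorm(n, sd = 0.5) > 0)
  })
  lambda <- 0.08
  cd <- sparsellgmn:::lasso_cd(x_mat, y, lambda)
  gn <- glmnet::glmnet(x_mat, y, lambda = lambda, standardize = FALSE,
                       intercept = TRUE, thresh = 1e-12)
  expect_equal(unname(cd$beta), as.numeric(gn$beta), tolerance = 1e-4)
})

test_that("lasso selection ranks a strong planted signal first", {
  hits <- 0L
  for (s in 1:10) {
    sig <- generate_sparse_signal(n = 80, p = 6, k = 1, d = 2, seed = 300 + s)
    ls <- lasso_select(sig$table, quick_config(n_folds = 4, seed = s))
    hits <- hits + (ls$ranking$index[1] == sig$truth)
  }
  expect_gte(hits, 8L)
})

test_that("lasso on pure noise selects almost nothing", {
  sizes <- vapply(1:6, function(s) {
    sig <- generate_sparse_signal(n = 60, p = 8, k = 0, d = 0, seed = 400 + s)
    length(lasso_select(sig$table, quick_config(n_folds = 3, seed = s))$selected)
  }, numeric(1))
  expect_lte(stats::median(sizes), 2)
})

test_that("lasso selection is deterministic under a fixed seed", {
  sig <- generate_sparse_signal(n = 50, p = 5, k = 2, d = 1.5, seed = 77)
  cfg <- quick_config(n_folds = 3, seed = 4)
  l1 <- lasso_select(sig$table, cfg)
  l2 <- lasso_select(sig$table, cfg)
  expect_identical(l1$ranking, l2$ranking)
  expect_identical(l1$oof, l2$oof)
})
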