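test_that("input expansion follows the quadratic log-linearization layout", {
  expect_equal(expand_input(c(2, 3)), c(1, 2, 3, 4, 6, 9))
  expect_equal(expand_input(rep(0, 3)), c(1, rep(0, 9)))
  expect_length(expand_input(rnorm(65)), 2211)  # 1 + 65 + 65*66/2
  expect_error(expand_input(c(1, Inf)), "finite")
})

test_that("zero weights give uniform posteriors for any mixture size", {
  for (m in c(1L, 3L)) {
    h <- 1 + 2 + 3  # D = 2
    model <- sparsellgmn:::new_llgmn(matrix(0, h, 2 * m), m, c("x1", "x2"))
    fw <- llgmn_forward(model, c(0.3, -1.2))
    expect_equal(fw$posterior, c(0.5, 0.5), tolerance = 1e-12)
    expect_equal(fw$units, rep(1 / (2 * m), 2 * m), tolerance = 1e-12)
  }
})

test_that("log-linearized network reproduces Bayes posteriors of the mixture", {
  # 1-D hand case: unit-variance classes at -1 and +1, equal priors, x = 1
  priors <- matrix(0.5, 2, 1)
  means <- array(c(-1, 1), dim = c(2, 1, 1))
  covs <- array(1, dim = c(2, 1, 1, 1))
  model <- log_linearize_gmm(priors, means, covs)
  post <- llgmn_forward(model, 1)$posterior
  expect_equal(post[2], 1 / (1 + exp(-2)), tolerance = 1e-9)
  expect_equal(llgmn_forward(model, 0)$posterior, c(0.5, 0.5), tolerance = 1e-9)

  # identical components for both classes: posteriors uniform everywhere
  same <- random_gmm(2, 1, 2)
  same$means[2, , ] <- same$means[1, , ]
  same$covariances[2, 1, , ] <- same$covariances[1, 1, , ]
  same$priors[] <- 0.25
  same$priors <- same$priors / sum(same$priors)
  m_same <- log_linearize_gmm(same$priors, same$means, same$covariances)
  expect_equal(llgmn_forward(m_same, c(1.7, -0.4))$posterior, c(0.5, 0.5),
               tolerance = 1e-9)

  # random SPD instances across dimensions and mixture sizes
  withr::with_seed(7, {
    for (d in 1:3) {
      for (m_n in 1:2) {
        g <- random_gmm(2, m_n, d)
        model <- log_linearize_gmm(g$priors, g$means, g$covariances)
        for (rep_i in 1:20) {
          x <- rnorm(d)
          expect_equal(llgmn_forward(model, x)$posterior,
                       gmm_bayes_posterior(g$priors, g$means, g$covariances, x),
                       tolerance = 1e-6)
        }
      }
    }
  })
  bad <- random_gmm(2, 1, 2)
  bad$covariances[1, 1, , ] <- matrix(0, 2, 2)
  expect_error(log_linearize_gmm(bad$priors, bad$means, bad$covariances),
               "positive definite")
})

test_that("cross-entropy matches hand evaluation and clips at zero posteriors", {
  h <- 1 + 2 + 3
  model <- sparsellgmn:::new_llgmn(matrix(0, h, 2), 1, c("v1", "v2"))
  tab <- make_gaussian_table(1, 2, seed = 5)  # one row per class
  expect_equal(cross_entropy(model, tab), -2 * log(0.5), tolerance = 1e-12)

  # posteriors (0.9, 0.1) and (0.2, 0.8): logistic posterior along x1 with
  # weight chosen per-row via a single-feature model evaluated at crafted x
  w <- matrix(0, 1 + 1 + 1, 2)
  w[2, 1] <- 1  # class-1 activation = x
  model1 <- sparsellgmn:::new_llgmn(w, 1, "v1")
  x1 <- log(0.9 / 0.1)
  x2 <- log(0.2 / 0.8)
  dat <- tibble::tibble(v1 = c(x1, x2), label = c("a", "b"))
  tab2 <- feature_table(dat, positive_class = "a")
  expect_equal(cross_entropy(model1, tab2), -log(0.9) - log(0.8),
               tolerance = 1e-9)
})

test_that("analytic gradient agrees with central finite differences", {
  withr::with_seed(11, {
    for (rep_i in 1:20) {
      d <- sample(1:3, 1)
      m_n <- sample(1:2, 1)
      n <- sample(3:6, 1)
      h <- 1 + d + d * (d + 1) / 2
      w_mat <- matrix(rnorm(h * 2 * m_n, sd = 0.5), h, 2 * m_n)
      w_mat[, 2 * m_n] <- 0
      vals <- matrix(rnorm(n * d), n, d)
      colnames(vals) <- paste0("v", seq_len(d))
      dat <- tibble::as_tibble(vals)
      dat$label <- sample(rep(c("a", "b"), length.out = n))
      tab <- feature_table(dat, positive_class = "a")
      model <- sparsellgmn:::new_llgmn(w_mat, m_n, colnames(vals))

      analytic <- llgmn_gradient(model, tab)
      numeric_g <- matrix(0, h, 2 * m_n)
      eps <- 1e-5
      for (i in seq_len(h)) {
        for (j in seq_len(2 * m_n - 1)) {  # anchored column excluded
          mp <- model; mp$weights[i, j] <- mp$weights[i, j] + eps
          mm <- model; mm$weights[i, j] <- mm$weights[i, j] - eps
          numeric_g[i, j] <- (cross_entropy(mp, tab) - cross_entropy(mm, tab)) /
            (2 * eps)
        }
      }
      denom <- max(abs(numeric_g), 1)
      expect_lt(max(abs(analytic - numeric_g)) / denom, 1e-4)
      expect_true(all(analytic[, 2 * m_n] == 0))
    }
  })
})

test_that("gradient vanishes at a saturated perfect fit", {
  h <- 1 + 1 + 1
  w <- matrix(0, h, 2)
  w[2, 1] <- 50  # huge logistic weight: posteriors saturate on the targets
  model <- sparsellgmn:::new_llgmn(w, 1, "v1")
  dat <- tibble::tibble(v1 = c(2, 1.5, -2, -1), label = c("a", "a", "b", "b"))
  tab <- feature_table(dat, positive_class = "a")
  expect_lt(max(abs(llgmn_gradient(model, tab))), 1e-6)
})

test_that("posteriors sum to one across random weights and inputs", {
  withr::with_seed(3, {
    for (rep_i in 1:1000) {
      d <- sample(1:4, 1)
      m_n <- sample(1:3, 1)
      h <- 1 + d + d * (d + 1) / 2
      w_mat <- matrix(rnorm(h * 2 * m_n, sd = 2), h, 2 * m_n)
      model <- sparsellgmn:::new_llgmn(w_mat, m_n, paste0("v", 1:d))
      post <- llgmn_forward(model, rnorm(d, sd = 3))$posterior
      expect_lt(abs(sum(post) - 1), 1e-9)
    }
  })
})

test_that("SGD training separates a two-Gaussian problem and is reproducible", {
  tab <- standardize(make_gaussian_table(50, 2, mu = 2, seed = 21))
  cfg <- quick_config(seed = 9)
  fit <- train_llgmn(tab, cfg)
  expect_lt(fit$loss, 0.1 * nrow(tab))  # well under chance; Bayes error ~ 0
  expect_lt(cross_entropy(fit, tab), 0.1 * nrow(tab))

  fit2 <- train_llgmn(tab, cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$trace, fit2$trace)

  # epoch-level loss is non-increasing nearly everywhere (SGD noise allowed)
  dec <- diff(fit$trace) <= 1e-8
  expect_gte(mean(dec), 0.95)

  fit0 <- train_llgmn(tab, analysis_config(max_epochs = 0, seed = 9))
  expect_true(all(fit0$weights == 0))
  expect_error(train_llgmn(tab[ft_labels(tab) == 1L, ], cfg))
})

test_that("models serialize to JSON and back", {
  tab <- standardize(make_gaussian_table(10, 2, seed = 2))
  fit <- train_llgmn(tab, quick_config(seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$weights, fit$weights)
  sp <- train_sparse_llgmn(tab, quick_config(lambda = 0.5, seed = 1))
  write_model_json(sp, path)
  back2 <- read_model_json(path)
  expect_s3_class(back2, "sparse_llgmn")
  expect_equal(unname(back2$w), unname(sp$w))
  expect_equal(predict(back2, tab), predict(sp, tab))
})
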