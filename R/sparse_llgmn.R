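#' Elementwise dimensionality-reduction layer
#'
#' The gating layer placed before the LLGMN: `y_i = w_i * x_i`.  A gate
#' stored as exactly zero makes the whole network output invariant to that
#' index, which is what turns L1-driven zeros into automatic index selection.
#'
#' @param w Length-P gate weights.
#' @param x Length-P input vector.
#' @return The gated length-P vector.
#' @export
reduce <- function(w, x) {
  if (length(w) != length(x)) abort("`w` and `x` must have equal length.")
  w * x
}

#' Soft-thresholding (proximal operator of the L1 norm)
#'
#' `sign(v) * max(|v| - t, 0)` applied elementwise.  Entries whose magnitude
#' falls below the threshold become exactly zero (no epsilon comparison),
#' which is the mechanism producing exact zeros in the trained gates.
#'
#' @param v Numeric vector.
#' @param t Non-negative threshold.
#' @return The thresholded vector.
#' @export
prox_l1 <- function(v, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) abort("`t` must be a single number >= 0.")
  sign(v) * pmax(abs(v) - t, 0)
}

new_sparse_llgmn <- function(w, llgmn, lambda, loss = NA_real_, epochs = 0L,
                             trace = numeric(), config = NULL) {
  structure(list(w = stats::setNames(as.numeric(w), llgmn$index_names),
                 weights = llgmn$weights,
                 n_classes = 2L,
                 n_components = llgmn$n_components,
                 index_names = llgmn$index_names,
                 lambda = lambda,
                 loss = loss,
                 epochs = epochs,
                 trace = trace,
                 config = config),
            class = c("sparse_llgmn", "llgmn"))
}

#' @export
print.sparse_llgmn <- function(x, ...) {
  cat(sprintf("<sparse_llgmn> P = %d indices (%d non-zero gates), M = %d, lambda = %g\n",
              length(x$w), sum(x$w != 0), x$n_components, x$lambda))
  if (is.finite(x$loss)) {
    cat(sprintf("training energy %.6g after %d epoch(s)\n", x$loss, x$epochs))
  }
  invisible(x)
}

#' Energy function of the sparse network
#'
#' The training objective: summed cross-entropy of the end-to-end posteriors
#' plus the L1 penalty `lambda * sum(|w_i|)` on the reduction-layer gates.
#'
#' @param model A `sparse_llgmn`.
#' @param table A standardized `feature_tbl`.
#' @return The scalar energy.
#' @export
energy <- function(model, table) {
  cross_entropy(model, table) + model$lambda * sum(abs(model$w))
}

#' Train the sparse LLGMN end-to-end
#'
#' Joint mini-batch SGD on the LLGMN weights and the reduction gates; after
#' every mini-batch step the gates receive the proximal L1 update
#' (soft-thresholding with threshold `learning_rate * lambda`), so
#' uninformative gates are driven to exact zeros.  Early stopping monitors
#' the full-data energy recomputed after each epoch, with the same rule as
#' [train_llgmn()]; the best-energy parameters are returned.  Gates start at
#' 1 (an identity layer), LLGMN weights at zero.
#'
#' @param table A standardized `feature_tbl` with both classes present.
#' @param config An [analysis_config()] whose `lambda` is a number (tune
#'   first with [tune_lambda_tpe()] if needed).
#' @param w_init Optional initial gate vector (default all ones).
#' @return A trained `sparse_llgmn`.
#' @export
train_sparse_llgmn <- function(table, config = analysis_config(), w_init = NULL) {
  check_trainable(table)
  if (identical(config$lambda, "tpe")) {
    abort("`config$lambda` is \"tpe\"; resolve it with tune_lambda_tpe() before training.")
  }
  vals <- ft_values(table)
  if (is.null(w_init)) w_init <- rep(1, ncol(vals))
  if (length(w_init) != ncol(vals)) abort("`w_init` must have one entry per index.")
  fit <- cpp_train(vals, ft_targets(table), config$n_components,
                   TRUE, as.double(w_init), config$lambda,
                   config$learning_rate, config$batch_size,
                   config$max_epochs, config$early_stop_min_delta,
                   config$early_stop_patience, config$seed)
  base <- new_llgmn(fit$W, config$n_components, colnames(vals))
  new_sparse_llgmn(fit$w, base, config$lambda,
                   loss = fit$loss, epochs = fit$epochs, trace = fit$trace,
                   config = config)
}

#' @export
predict.sparse_llgmn <- function(object, newdata, ...) {
  post <- posterior_matrix(object, newdata)
  tibble::tibble(p_class1 = post[, 1], p_class2 = post[, 2])
}

#' Tune the L1 coefficient with a tree-structured Parzen estimator
#'
#' Searches `lambda` over a log-uniform range, scoring each trial by the
#' mean per-sample out-of-fold cross-entropy of an inner stratified
#' cross-validation on `table`.  The TPE sampler and the inner folds are
#' seeded, so the same seed returns the same `lambda`.
#'
#' @param table A standardized `feature_tbl` (the training data of the
#'   enclosing fold, when tuning inside cross-validation).
#' @param config An [analysis_config()]; its `tpe` entry supplies the search
#'   range and budget unless overridden here.
#' @param low,high Search range (0 < low <= high).
#' @param n_trials Number of TPE trials.
#' @param inner_folds Folds of the inner objective CV.
#' @param seed Seed; defaults to `config$seed`.
#' @return The best `lambda`, with the trial history as attribute
#'   `"trials"` (a tibble with `lambda` and `objective`).
#' @export
tune_lambda_tpe <- function(table, config = analysis_config(),
                            low = config$tpe$low, high = config$tpe$high,
                            n_trials = config$tpe$n_trials,
                            inner_folds = config$tpe$inner_folds,
                            seed = config$seed) {
  check_trainable(table)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || low > high) {
    abort("Need 0 < low <= high for the lambda search range.")
  }
  if (n_trials < 1L) abort("`n_trials` must be >= 1.")
  labels <- ft_labels(table)
  inner_folds <- min(inner_folds, nrow(table))
  folds <- make_folds(labels, inner_folds, seed = child_seed(seed, 77L))

  objective <- function(lambda) {
    total <- 0
    for (k in sort(unique(folds))) {
      tr <- ft_subset_rows(table, folds != k)
      va <- ft_subset_rows(table, folds == k)
      cfg <- config
      cfg$lambda <- lambda
      cfg$seed <- child_seed(seed, 1000L + k)
      fit <- train_sparse_llgmn(tr, cfg)
      total <- total + cross_entropy(fit, va)
    }
    total / nrow(table)
  }

  res <- tpe_optimize(objective, low, high, n_trials,
                      seed = child_seed(seed, 7L))
  structure(res$best, trials = res$trials)
}
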