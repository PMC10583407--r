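# Comparison methods: stepwise backward elimination driven by partial
# Kullback-Leibler information of a trained LLGMN, leave-one-out AUC-drop
# importance, and Lasso regression fitted by cyclic coordinate descent.

#' Partial Kullback-Leibler information of one index
#'
#' Operationalized as the increase in summed cross-entropy when column `i`
#' is replaced by its training mean -- zero after standardization -- while
#' everything else is left intact.  An index the trained network ignores
#' scores exactly 0; negative values are possible and legal.
#'
#' @param model A trained `llgmn`.
#' @param table A standardized `feature_tbl`.
#' @param index Index name or position.
#' @return The scalar cross-entropy increase.
#' @export
partial_kli <- function(model, table, index) {
  vals <- ft_values(table)[, model$index_names, drop = FALSE]
  if (is.character(index)) index <- match(index, colnames(vals))
  if (is.na(index) || index < 1L || index > ncol(vals)) abort("Unknown index.")
  targets <- ft_targets(table)
  e0 <- ce_of_values(model, vals, targets)
  vals[, index] <- 0
  ce_of_values(model, vals, targets) - e0
}

# plain-LLGMN cross-validation: per-fold standardization, pooled OOF
# posteriors; shared helper of the stepwise and AUC-drop baselines
cv_llgmn_oof <- function(table, config, folds) {
  n <- nrow(table)
  k <- max(folds)
  models <- vector("list", k)
  std_params <- vector("list", k)
  oof <- rep(NA_real_, n)
  pre_std <- ft_is_standardized(table)
  for (f in seq_len(k)) {
    tr <- ft_subset_rows(table, folds != f)
    va <- ft_subset_rows(table, folds == f)
    if (!pre_std) {
      tr <- standardize(tr, zero_sd = "center")
      va <- apply_standardization(va, ft_std_params(tr))
    }
    cfg <- config
    cfg$seed <- child_seed(config$seed, f)
    fit <- train_llgmn(tr, cfg)
    models[[f]] <- fit
    std_params[[f]] <- ft_std_params(tr)
    oof[folds == f] <- predict(fit, va)$p_class1
  }
  list(models = models, std_params = std_params, oof = oof)
}

#' Stepwise index elimination by partial KLI
#'
#' The discrete baseline: starting from all indices, repeatedly (1) train an
#' LLGMN by cross-validation on the current set, (2) record the pooled
#' out-of-fold AUC, (3) compute the fold-averaged partial KLI of every
#' remaining index on the held-out rows, and (4) drop the index with the
#' smallest partial KLI.  The loop runs down to a single index (P - 1
#' removals); the selected set is the one maximizing the CV AUC along the
#' trace (ties go to the smaller set).
#'
#' @param table A `feature_tbl` with at least two indices.
#' @param config An [analysis_config()].
#' @param folds Optional shared fold assignment.
#' @return A `stepwise_trace`: a `trace` tibble (step, n_indices, auc,
#'   removed), the per-step index `sets`, the `selected` set, and the
#'   pooled out-of-fold posteriors of the selected step (`oof_selected`).
#' @export
stepwise_kli_selection <- function(table, config = analysis_config(), folds = NULL) {
  if (!inherits(table, "feature_tbl")) abort("`table` must be a feature_tbl.")
  if (!is.null(config$feature_subset)) {
    table <- ft_subset_indices(table, config$feature_subset)
  }
  p <- length(ft_index_names(table))
  if (p < 2L) abort("Stepwise elimination needs at least two indices.")
  labels <- ft_labels(table)
  if (is.null(folds)) folds <- make_folds(labels, config$n_folds, config$seed)
  k <- max(folds)

  current <- ft_index_names(table)
  steps <- list()
  sets <- list()
  oof_by_step <- list()
  step <- 0L
  while (length(current) >= 1L) {
    step <- step + 1L
    sub <- ft_subset_indices(table, current)
    cv <- cv_llgmn_oof(sub, config, folds)
    auc <- roc_analysis(cv$oof, labels)$auc
    sets[[step]] <- current
    oof_by_step[[step]] <- cv$oof
    removed <- NA_character_
    if (length(current) > 1L) {
      kli <- matrix(0, nrow = k, ncol = length(current),
                    dimnames = list(NULL, current))
      for (f in seq_len(k)) {
        va <- ft_subset_rows(sub, folds == f)
        if (!ft_is_standardized(sub)) {
          va <- apply_standardization(va, cv$std_params[[f]])
        }
        for (i in seq_along(current)) {
          kli[f, i] <- partial_kli(cv$models[[f]], va, current[i])
        }
      }
      removed <- current[which.min(colMeans(kli))]
      current <- setdiff(current, removed)
    } else {
      current <- character(0)
    }
    steps[[step]] <- tibble::tibble(step = step,
                                    n_indices = length(sets[[step]]),
                                    auc = auc,
                                    removed = removed)
  }
  trace <- dplyr::bind_rows(steps)
  # max AUC along the trace; on ties prefer the smaller set (later step)
  best_step <- with(trace, which(auc == max(auc)))
  best_step <- best_step[length(best_step)]
  structure(list(trace = trace,
                 sets = sets,
                 selected = sets[[best_step]],
                 best_step = best_step,
                 oof_selected = oof_by_step[[best_step]],
                 folds = folds,
                 config = config),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("<stepwise_trace> %d steps; selected %d indices (CV AUC %.3f)\n",
              nrow(x$trace), length(x$selected), x$trace$auc[x$best_step]))
  invisible(x)
}

#' Leave-one-out AUC-drop importance
#'
#' For a selected index set: the pooled out-of-fold AUC with the full set is
#' the baseline; deleting each index in turn and re-running the
#' cross-validation gives the AUC without it, reported as the percentage
#' reduction `(AUC_full - AUC_without) / AUC_full * 100` (negative values
#' mean the AUC improved on deletion).
#'
#' @param table A `feature_tbl` restricted to the selected set (>= 2
#'   indices).
#' @param config An [analysis_config()].
#' @param folds Optional shared fold assignment.
#' @return A tibble (index, auc_without, auc_reduction_pct) sorted by
#'   descending reduction, with the baseline AUC as attribute `"auc_full"`.
#' @export
auc_drop_importance <- function(table, config = analysis_config(), folds = NULL) {
  if (!is.null(config$feature_subset)) {
    table <- ft_subset_indices(table, config$feature_subset)
  }
  idx <- ft_index_names(table)
  if (length(idx) < 2L) abort("AUC-drop importance needs at least two indices.")
  labels <- ft_labels(table)
  if (is.null(folds)) folds <- make_folds(labels, config$n_folds, config$seed)
  auc_full <- roc_analysis(cv_llgmn_oof(table, config, folds)$oof, labels)$auc
  auc_without <- vapply(idx, function(i) {
    sub <- ft_subset_indices(table, setdiff(idx, i))
    roc_analysis(cv_llgmn_oof(sub, config, folds)$oof, labels)$auc
  }, numeric(1))
  out <- tibble::tibble(index = idx,
                        auc_without = unname(auc_without),
                        auc_reduction_pct = 100 * (auc_full - auc_without) / auc_full)
  out <- dplyr::arrange(out, dplyr::desc(.data$auc_reduction_pct))
  attr(out, "auc_full") <- auc_full
  out
}

soft_thresh <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# cyclic coordinate descent for (1/2N)||y - b0 - X b||^2 + lambda ||b||_1;
# X columns are centered (standardized), so b0 = mean(y) exactly
lasso_cd <- function(x_mat, y, lambda, beta = NULL, tol = 1e-8,
                     max_iter = 100000L) {
  if (is.null(beta)) beta <- rep(0, ncol(x_mat))
  fit <- cpp_lasso_cd(x_mat, y, lambda, beta, tol, max_iter)
  list(beta = drop(fit$beta), intercept = fit$intercept)
}

#' Lasso regression on a standardized feature table
#'
#' Minimizes `(1/2N) * sum((y - b0 - x' beta)^2) + lambda * sum(|beta|)` by
#' cyclic coordinate descent (coefficient tolerance 1e-8), with the
#' positive class coded 1 and the negative class 0.  On standardized
#' predictors the coefficients are the standardized partial regression
#' coefficients used for the importance ranking; the linear predictor is
#' the ROC score.
#'
#' @param table A standardized `feature_tbl`.
#' @param lambda Non-negative penalty.
#' @return A `lasso_fit` with named `coefficients`, `intercept`, `lambda`.
#' @export
lasso_fit <- function(table, lambda) {
  if (!ft_is_standardized(table)) abort("`table` must be standardized.")
  if (!is.numeric(lambda) || lambda < 0) abort("`lambda` must be >= 0.")
  x_mat <- ft_values(table)
  y <- as.numeric(ft_labels(table) == 1L)
  fit <- lasso_cd(x_mat, y, lambda)
  structure(list(coefficients = stats::setNames(fit$beta, colnames(x_mat)),
                 intercept = fit$intercept,
                 lambda = lambda),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> lambda = %g, %d of %d coefficients non-zero\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  vals <- ft_values(newdata)[, names(object$coefficients), drop = FALSE]
  drop(object$intercept + vals %*% object$coefficients)
}

# glmnet-style penalty path: from the all-zero threshold down
lasso_lambda_path <- function(x_mat, y, n_lambda = 50L, eps = 1e-3) {
  lmax <- max(abs(crossprod(x_mat, y - mean(y)))) / nrow(x_mat)
  exp(seq(log(lmax), log(lmax * eps), length.out = n_lambda))
}

# pick lambda by inner CV mean squared error (plain minimum, seeded folds)
lasso_pick_lambda <- function(table, config, inner_folds = 5L, seed = 1L) {
  x_mat <- ft_values(table)
  y <- as.numeric(ft_labels(table) == 1L)
  path <- lasso_lambda_path(x_mat, y)
  folds <- make_folds(ft_labels(table), min(inner_folds, nrow(table)), seed)
  mse <- numeric(length(path))
  for (f in sort(unique(folds))) {
    xtr <- x_mat[folds != f, , drop = FALSE]
    ytr <- y[folds != f]
    xva <- x_mat[folds == f, , drop = FALSE]
    yva <- y[folds == f]
    beta <- NULL
    for (li in seq_along(path)) {
      cd <- lasso_cd(xtr, ytr, path[li], beta = beta)
      beta <- cd$beta
      pred <- cd$intercept + drop(xva %*% beta)
      mse[li] <- mse[li] + sum((yva - pred)^2)
    }
  }
  path[which.min(mse)]
}

#' Lasso-based index selection with out-of-fold scores
#'
#' Runs the Lasso baseline the same way the network methods are run: for
#' each outer fold the training rows are standardized, `lambda` is chosen by
#' an inner 5-fold cross-validation minimizing squared error, and the
#' held-out rows are scored by the linear predictor.  A full-data fit (with
#' its own inner-CV `lambda`) provides the standardized coefficients used
#' for the importance ranking by `|beta|`.
#'
#' @param table A `feature_tbl`.
#' @param config An [analysis_config()].
#' @param folds Optional shared outer fold assignment.
#' @return A `lasso_selection`: full-data `fit`, `ranking` tibble
#'   (index, beta, abs_beta), `selected` (non-zero coefficients), and the
#'   `oof` tibble of out-of-fold linear predictors.
#' @export
lasso_select <- function(table, config = analysis_config(), folds = NULL) {
  if (!is.null(config$feature_subset)) {
    table <- ft_subset_indices(table, config$feature_subset)
  }
  labels <- ft_labels(table)
  if (is.null(folds)) folds <- make_folds(labels, config$n_folds, config$seed)
  n <- nrow(table)
  oof <- rep(NA_real_, n)
  pre_std <- ft_is_standardized(table)
  for (f in sort(unique(folds))) {
    tr <- ft_subset_rows(table, folds != f)
    va <- ft_subset_rows(table, folds == f)
    if (!pre_std) {
      tr <- standardize(tr, zero_sd = "center")
      va <- apply_standardization(va, ft_std_params(tr))
    }
    lam <- lasso_pick_lambda(tr, config, seed = child_seed(config$seed, 300L + f))
    fit_f <- lasso_fit(tr, lam)
    oof[folds == f] <- predict(fit_f, va)
  }
  full <- if (pre_std) table else standardize(table, zero_sd = "center")
  lam_full <- lasso_pick_lambda(full, config, seed = child_seed(config$seed, 299L))
  fit <- lasso_fit(full, lam_full)
  ranking <- tibble::tibble(index = names(fit$coefficients),
                            beta = unname(fit$coefficients),
                            abs_beta = abs(unname(fit$coefficients)))
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$abs_beta))
  structure(list(fit = fit,
                 ranking = ranking,
                 selected = ranking$index[ranking$abs_beta > 0],
                 oof = tibble::tibble(row = seq_len(n), fold = folds,
                                      label = labels, score = oof),
                 folds = folds,
                 config = config),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("<lasso_selection> lambda = %g, %d indices selected\n",
              x$fit$lambda, length(x$selected)))
  invisible(x)
}
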