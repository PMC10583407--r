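#' Stratified cross-validation folds
#'
#' Partitions participants into K folds so that the per-class counts of any
#' two folds differ by at most one, while keeping total fold sizes as equal
#' as possible (classes hand their "extra" members to the currently smallest
#' folds).  The shuffle is seeded.
#'
#' @param labels Length-N class labels (any type with two or more values).
#' @param k Number of folds, `k <= N`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per participant.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k > n) abort(sprintf("Cannot make %d folds from %d participants.", k, n))
  if (k < 2L) abort("`k` must be at least 2.")
  fold <- integer(n)
  totals <- numeric(k)
  with_seed(seed, {
    classes <- names(sort(table(labels), decreasing = TRUE))
    for (cl in classes) {
      members <- which(as.character(labels) == cl)
      n_c <- length(members)
      if (n_c < k) {
        warn(sprintf("Class '%s' has %d member(s) for %d folds; some folds get none.",
                     cl, n_c, k))
      }
      base <- n_c %/% k
      extra <- n_c %% k
      counts <- rep(base, k)
      if (extra > 0) {
        # folds currently lightest take one extra member each (random ties)
        order_f <- order(totals + runif(k) * 1e-9)
        counts[order_f[seq_len(extra)]] <- base + 1L
      }
      members <- members[sample.int(n_c)]
      fold[members] <- rep(seq_len(k), times = counts)
      totals <- totals + counts
    }
  })
  fold
}

#' Cross-validated training of the sparse network
#'
#' For each fold: standardize on the training rows only, tune `lambda` (when
#' the config says `"tpe"`), train the sparse network, and score the held-out
#' rows with their training-fold standardization.  Out-of-fold posteriors of
#' the positive class are assembled over all participants.
#'
#' @param table A `feature_tbl` (unstandardized; per-fold standardization is
#'   applied internally).  A table standardized beforehand is accepted and
#'   used as-is, which reproduces the global-standardization variant.
#' @param config An [analysis_config()].
#' @param folds Optional precomputed fold assignment (shared folds keep
#'   DeLong comparisons paired across methods); default from [make_folds()].
#' @return An `llgmn_cv` object: per-fold models, a K x P gate-weight
#'   matrix, the fold assignment, per-fold standardization parameters and
#'   tuned lambdas, and an `oof` tibble (row, fold, label, posterior).
#' @export
cross_validate <- function(table, config = analysis_config(), folds = NULL) {
  if (!inherits(table, "feature_tbl")) abort("`table` must be a feature_tbl.")
  if (!is.null(config$feature_subset)) {
    table <- ft_subset_indices(table, config$feature_subset)
  }
  n <- nrow(table)
  if (n < config$n_folds) abort("Fewer participants than folds.")
  labels <- ft_labels(table)
  if (is.null(folds)) folds <- make_folds(labels, config$n_folds, config$seed)
  k <- max(folds)
  p <- length(ft_index_names(table))
  pre_standardized <- ft_is_standardized(table)

  models <- vector("list", k)
  std_params <- vector("list", k)
  lambdas <- numeric(k)
  weights <- matrix(0, nrow = k, ncol = p,
                    dimnames = list(NULL, ft_index_names(table)))
  oof <- rep(NA_real_, n)

  for (f in seq_len(k)) {
    tr <- ft_subset_rows(table, folds != f)
    va <- ft_subset_rows(table, folds == f)
    if (!pre_standardized) {
      tr <- tryCatch(standardize(tr, zero_sd = "center"), error = function(e) {
        abort(sprintf("Fold %d: %s", f, conditionMessage(e)))
      })
      va <- apply_standardization(va, ft_std_params(tr))
    }
    cfg <- config
    cfg$seed <- child_seed(config$seed, f)
    if (identical(config$lambda, "tpe")) {
      cfg$lambda <- as.numeric(tune_lambda_tpe(tr, cfg))
    }
    fit <- tryCatch(train_sparse_llgmn(tr, cfg), error = function(e) {
      abort(sprintf("Fold %d: %s", f, conditionMessage(e)))
    })
    models[[f]] <- fit
    std_params[[f]] <- ft_std_params(tr)
    lambdas[f] <- cfg$lambda
    weights[f, ] <- fit$w
    oof[folds == f] <- predict(fit, va)$p_class1
  }

  structure(list(folds = folds,
                 models = models,
                 weights = weights,
                 lambdas = lambdas,
                 std_params = std_params,
                 oof = tibble::tibble(row = seq_len(n), fold = folds,
                                      label = labels, posterior = oof),
                 index_names = ft_index_names(table),
                 pre_standardized = pre_standardized,
                 config = config),
            class = "llgmn_cv")
}

#' @export
print.llgmn_cv <- function(x, ...) {
  cat(sprintf("<llgmn_cv> %d folds, %d participants, %d indices\n",
              max(x$folds), length(x$folds), length(x$index_names)))
  cat(sprintf("out-of-fold AUC %.3f; lambda %s\n",
              roc_analysis(x$oof$posterior, x$oof$label)$auc,
              paste(signif(unique(x$lambdas), 3), collapse = ", ")))
  invisible(x)
}

#' Index selection from cross-validated gate weights
#'
#' An index is judged effective when its reduction-layer gate was non-zero
#' in at least one fold.  The report carries the per-index signed mean gate,
#' the mean absolute gate (used for the ranking, which avoids sign
#' cancellation across folds), and the number of folds with a non-zero gate.
#'
#' @param cv An `llgmn_cv` from [cross_validate()].
#' @return A `selection_result` with `selected` (character vector) and a
#'   per-index `weights` tibble ordered by descending mean absolute gate.
#' @export
select_indices <- function(cv) {
  if (!inherits(cv, "llgmn_cv")) abort("`cv` must come from cross_validate().")
  w <- cv$weights
  tab <- tibble::tibble(index = colnames(w),
                        mean_w = unname(colMeans(w)),
                        mean_abs_w = unname(colMeans(abs(w))),
                        n_folds_nonzero = unname(colSums(w != 0)))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$mean_abs_w))
  structure(list(selected = tab$index[tab$n_folds_nonzero > 0],
                 weights = tab,
                 ranking = tab$index),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d indices selected\n",
              length(x$selected), nrow(x$weights)))
  print(head(x$weights, 10))
  invisible(x)
}

#' Permutation importance of each index
#'
#' Computes the validation cross-entropy `e` on the intact table, then for
#' each index shuffles that column across the validation rows (seeded),
#' recomputes the error `e_i`, and reports `PI_i = e_i - e`.  With
#' `repeats > 1` the mean over independent shuffles is returned.  An index
#' whose gate is zero leaves the posterior untouched, so its PI is exactly 0.
#'
#' @param model A trained `sparse_llgmn` (or `llgmn`).
#' @param val_table Validation `feature_tbl`, standardized with the model's
#'   training-fold parameters.
#' @param seed Integer seed for the shuffles.
#' @param repeats Shuffles per index (default 1, the single-pass algorithm).
#' @return A tibble with `index` and `pi`.
#' @export
permutation_importance <- function(model, val_table, seed = 1L, repeats = 1L) {
  if (nrow(val_table) < 1L) abort("Validation table is empty.")
  vals <- ft_values(val_table)[, model$index_names, drop = FALSE]
  targets <- ft_targets(val_table)
  e_base <- ce_of_values(model, vals, targets)
  p <- ncol(vals)
  pi_vals <- numeric(p)
  with_seed(seed, {
    for (i in seq_len(p)) {
      acc <- 0
      for (r in seq_len(repeats)) {
        perm <- sample.int(nrow(vals))
        shuffled <- vals
        shuffled[, i] <- vals[perm, i]
        acc <- acc + ce_of_values(model, shuffled, targets) - e_base
      }
      pi_vals[i] <- acc / repeats
    }
  })
  tibble::tibble(index = colnames(vals), pi = pi_vals)
}

ce_of_values <- function(model, vals, targets) {
  if (inherits(model, "sparse_llgmn")) vals <- sweep(vals, 2, model$w, "*")
  cpp_cross_entropy(cpp_expand(vals), model$weights, model$n_components, targets)
}

#' Aggregate permutation importance across folds
#'
#' Replays each fold of a cross-validation: the held-out rows are
#' standardized with that fold's training parameters and scored by the
#' fold's model with [permutation_importance()].  The final evaluation is
#' the arithmetic mean over folds.
#'
#' @param cv An `llgmn_cv`.
#' @param table The `feature_tbl` the CV was run on.
#' @param repeats Shuffles per index per fold.
#' @return An `importance_report` with the K x P `pi_matrix` and a tibble
#'   of per-index means.
#' @export
aggregate_importance <- function(cv, table, repeats = 1L) {
  if (!is.null(cv$config$feature_subset)) {
    table <- ft_subset_indices(table, cv$config$feature_subset)
  }
  k <- max(cv$folds)
  p <- length(cv$index_names)
  pi_matrix <- matrix(0, nrow = k, ncol = p,
                      dimnames = list(NULL, cv$index_names))
  for (f in seq_len(k)) {
    va <- ft_subset_rows(table, cv$folds == f)
    if (!cv$pre_standardized) {
      va <- apply_standardization(va, cv$std_params[[f]])
    }
    pi_matrix[f, ] <- permutation_importance(cv$models[[f]], va,
                                             seed = child_seed(cv$config$seed, 500L + f),
                                             repeats = repeats)$pi
  }
  structure(list(pi_matrix = pi_matrix,
                 importance = tibble::tibble(index = cv$index_names,
                                             pi_mean = unname(colMeans(pi_matrix)))),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %d folds x %d indices\n",
              nrow(x$pi_matrix), ncol(x$pi_matrix)))
  print(head(dplyr::arrange(x$importance, dplyr::desc(.data$pi_mean)), 10))
  invisible(x)
}
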