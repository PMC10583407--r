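# broom-style tidy()/glance() methods for the fitted objects

#' @exportS3Method generics::tidy
tidy.sparse_llgmn <- function(x, ...) {
  tibble::tibble(index = x$index_names,
                 w = unname(x$w),
                 abs_w = abs(unname(x$w)),
                 selected = unname(x$w) != 0)
}

#' @exportS3Method generics::glance
glance.sparse_llgmn <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 n_indices = length(x$w),
                 n_nonzero = sum(x$w != 0),
                 energy = x$loss,
                 epochs = x$epochs)
}

#' @exportS3Method generics::glance
glance.llgmn <- function(x, ...) {
  tibble::tibble(n_indices = length(x$index_names),
                 n_components = x$n_components,
                 cross_entropy = x$loss,
                 epochs = x$epochs)
}

#' @exportS3Method generics::tidy
tidy.llgmn_cv <- function(x, ...) {
  w <- x$weights
  tibble::as_tibble(w) |>
    dplyr::mutate(fold = dplyr::row_number()) |>
    tidyr::pivot_longer(-"fold", names_to = "index", values_to = "w")
}

#' @exportS3Method generics::glance
glance.llgmn_cv <- function(x, ...) {
  tibble::tibble(n_folds = max(x$folds),
                 n_participants = length(x$folds),
                 oof_auc = roc_analysis(x$oof$posterior, x$oof$label)$auc,
                 mean_lambda = mean(x$lambdas),
                 n_selected = sum(colSums(x$weights != 0) > 0))
}

#' @exportS3Method generics::tidy
tidy.selection_result <- function(x, ...) x$weights

#' @exportS3Method generics::tidy
tidy.importance_report <- function(x, ...) {
  tibble::as_tibble(x$pi_matrix) |>
    dplyr::mutate(fold = dplyr::row_number()) |>
    tidyr::pivot_longer(-"fold", names_to = "index", values_to = "pi")
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc,
                 best_threshold = x$best_threshold,
                 sensitivity = x$sens_at_best,
                 specificity = x$spec_at_best,
                 n_pos = x$n_pos,
                 n_neg = x$n_neg)
}

#' @exportS3Method generics::tidy
tidy.lasso_fit <- function(x, ...) {
  tibble::tibble(index = names(x$coefficients),
                 beta = unname(x$coefficients),
                 abs_beta = abs(unname(x$coefficients)))
}

#' @exportS3Method generics::glance
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda,
                 intercept = x$intercept,
                 n_nonzero = sum(x$coefficients != 0))
}

#' @exportS3Method generics::tidy
tidy.stepwise_trace <- function(x, ...) x$trace

#' @exportS3Method generics::tidy
tidy.bm_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p,
                 relative_effect = x$relative_effect)
}

#' @exportS3Method generics::tidy
tidy.delong_result <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, statistic = x$z,
                 p.value = x$p, se = x$se)
}
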