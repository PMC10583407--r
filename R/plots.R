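# ggplot2 autoplot methods for the result objects

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  pts <- dplyr::arrange(object$points, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.llgmn_cv <- function(object, ...) {
  dat <- tidy.llgmn_cv(object)
  keep <- dat |>
    dplyr::group_by(.data$index) |>
    dplyr::filter(any(.data$w != 0)) |>
    dplyr::ungroup()
  ord <- keep |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(m = mean(abs(.data$w)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m))
  keep$index <- factor(keep$index, levels = ord$index)
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$index, y = .data$w)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = NULL, y = "Reduction-layer weight w",
                  title = "Selected indices: gate weights across folds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.importance_report <- function(object, ...) {
  dat <- tidy.importance_report(object)
  ord <- object$importance |>
    dplyr::arrange(dplyr::desc(.data$pi_mean))
  dat$index <- factor(dat$index, levels = ord$index)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = .data$pi)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4) +
    ggplot2::labs(x = NULL, y = "Permutation importance",
                  title = "Permutation importance across folds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.stepwise_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$n_indices, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$trace$n_indices[object$best_step],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Indices remaining", y = "Pooled out-of-fold AUC",
                  title = "Stepwise partial-KLI elimination") +
    ggplot2::theme_minimal()
}

#' Overlayed ROC curves of a multi-method run
#'
#' @param report A `run_report` from [run_full_analysis()].
#' @return A ggplot object.
#' @export
plot_run_roc <- function(report) {
  dat <- dplyr::bind_rows(lapply(names(report$methods), function(m) {
    r <- report$methods[[m]]$roc
    dplyr::mutate(r$points,
                  method = sprintf("%s (AUC %.3f)", method_labels[[m]], r$auc))
  }))
  dat <- dplyr::arrange(dat, .data$method, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(dat, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity,
                                    colour = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
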