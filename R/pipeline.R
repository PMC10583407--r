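# End-to-end orchestration: shared folds across methods, per-method
# selection/importance/ROC, paired DeLong comparisons, and report output.

method_labels <- c(proposed = "sparse network",
                   kli = "stepwise partial KLI",
                   lasso = "Lasso regression")

#' Run the full multi-method analysis
#'
#' Executes the selected methods on one feature table with a single shared
#' stratified fold assignment, so the out-of-fold scores are paired and the
#' DeLong comparisons are valid.  Per method it produces the selected index
#' set, an importance table (permutation importance for the sparse network,
#' AUC-drop for stepwise partial KLI, standardized coefficients for Lasso),
#' the pooled out-of-fold ROC analysis with the
#' maximum-sensitivity-plus-specificity threshold, and the confusion table
#' with Fisher's exact p and Yule's Q at that threshold.
#'
#' @param table A `feature_tbl`.
#' @param config An [analysis_config()].
#' @param methods Subset of `c("proposed", "kli", "lasso")`.
#' @param tpe_scope For the proposed method with `lambda = "tpe"`: tune
#'   once on the full (standardized) table (`"global"`, default) or inside
#'   every cross-validation fold (`"per_fold"`).
#' @param outdir Optional directory; when given, all artifacts (report JSON,
#'   fold assignment, per-method ROC points, selections, importances) are
#'   written as CSV/JSON.
#' @return A `run_report` list: `methods` (per-method results), `delong`
#'   (pairwise comparisons with raw and Holm-adjusted p, when >= 2
#'   methods), `folds`, `config`, `timing`.
#' @export
run_full_analysis <- function(table, config = analysis_config(),
                              methods = c("proposed", "kli", "lasso"),
                              tpe_scope = c("global", "per_fold"),
                              outdir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  tpe_scope <- match.arg(tpe_scope)
  if (!inherits(table, "feature_tbl")) abort("`table` must be a feature_tbl.")
  if (!is.null(config$feature_subset)) {
    table <- ft_subset_indices(table, config$feature_subset)
    config$feature_subset <- NULL
  }
  labels <- ft_labels(table)
  folds <- make_folds(labels, config$n_folds, config$seed)
  t0 <- proc.time()[["elapsed"]]
  results <- list()

  for (m in methods) {
    tm <- proc.time()[["elapsed"]]
    res <- switch(
      m,
      proposed = {
        cfg <- config
        if (identical(cfg$lambda, "tpe") && tpe_scope == "global") {
          cfg$lambda <- as.numeric(
            tune_lambda_tpe(standardize(table, zero_sd = "center"), cfg))
        }
        cv <- cross_validate(table, cfg, folds = folds)
        sel <- select_indices(cv)
        imp <- aggregate_importance(cv, table)
        list(scores = cv$oof$posterior,
             selected = sel$selected,
             selection = sel,
             importance = dplyr::arrange(imp$importance,
                                         dplyr::desc(.data$pi_mean)),
             detail = list(cv = cv, importance_report = imp,
                           lambda = cv$lambdas))
      },
      kli = {
        st <- stepwise_kli_selection(table, config, folds = folds)
        imp <- if (length(st$selected) >= 2L) {
          auc_drop_importance(ft_subset_indices(table, st$selected),
                              config, folds = folds)
        } else {
          tibble::tibble(index = st$selected, auc_without = NA_real_,
                         auc_reduction_pct = NA_real_)
        }
        list(scores = st$oof_selected,
             selected = st$selected,
             importance = imp,
             detail = list(trace = st$trace, best_step = st$best_step))
      },
      lasso = {
        ls <- lasso_select(table, config, folds = folds)
        list(scores = ls$oof$score,
             selected = ls$selected,
             importance = ls$ranking,
             detail = list(lambda = ls$fit$lambda, fit = ls$fit))
      })
    roc <- roc_analysis(res$scores, labels)
    predicted <- res$scores >= roc$best_threshold
    assoc <- confusion_and_association(predicted, labels == 1L)
    res$roc <- roc
    res$association <- assoc
    res$seconds <- proc.time()[["elapsed"]] - tm
    results[[m]] <- res
  }

  delong <- NULL
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]
      b <- pairs[2, i]
      dl <- delong_test(results[[a]]$scores, results[[b]]$scores, labels)
      tibble::tibble(method_a = a, method_b = b, auc_a = dl$auc_a,
                     auc_b = dl$auc_b, z = dl$z, p_raw = dl$p)
    })
    delong <- dplyr::bind_rows(rows)
    delong$p_holm <- holm_adjust(delong$p_raw)
  }

  report <- structure(list(methods = results,
                           delong = delong,
                           folds = folds,
                           labels = labels,
                           config = config,
                           tpe_scope = tpe_scope,
                           timing = proc.time()[["elapsed"]] - t0),
                      class = "run_report")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d method(s), %d participants, %d folds (%.1f s)\n",
              length(x$methods), length(x$folds), max(x$folds), x$timing))
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    cat(sprintf("  %-22s AUC %.3f  sens %.3f  spec %.3f  |selected| = %d  Yule Q %s\n",
                method_labels[[m]], r$roc$auc, r$roc$sens_at_best,
                r$roc$spec_at_best, length(r$selected),
                if (r$association$q_defined) sprintf("%.3f", r$association$yule_q) else "NA"))
  }
  if (!is.null(x$delong)) {
    for (i in seq_len(nrow(x$delong))) {
      cat(sprintf("  DeLong %s vs %s: p = %.4g (Holm %.4g)\n",
                  x$delong$method_a[i], x$delong$method_b[i],
                  x$delong$p_raw[i], x$delong$p_holm[i]))
    }
  }
  invisible(x)
}

#' Summarize a run report as a tibble
#'
#' @param x A `run_report`.
#' @param ... Unused.
#' @return One row per method: AUC, threshold, sensitivity, specificity,
#'   Fisher p, Yule's Q, number of selected indices, seconds.
#' @exportS3Method generics::tidy
tidy.run_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$methods), function(m) {
    r <- x$methods[[m]]
    tibble::tibble(method = m,
                   auc = r$roc$auc,
                   threshold = r$roc$best_threshold,
                   sensitivity = r$roc$sens_at_best,
                   specificity = r$roc$spec_at_best,
                   fisher_p = r$association$fisher_p,
                   yule_q = r$association$yule_q,
                   n_selected = length(r$selected),
                   seconds = r$seconds)
  }))
}

write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::tibble(row = seq_along(report$folds),
                                  fold = report$folds,
                                  label = report$labels),
                   file.path(outdir, "folds.csv"))
  for (m in names(report$methods)) {
    r <- report$methods[[m]]
    readr::write_csv(r$roc$points, file.path(outdir, sprintf("roc_%s.csv", m)))
    readr::write_csv(r$importance, file.path(outdir, sprintf("importance_%s.csv", m)))
    sel_tab <- if (m == "proposed") r$selection$weights else
      tibble::tibble(index = r$selected)
    readr::write_csv(sel_tab, file.path(outdir, sprintf("selected_%s.csv", m)))
    readr::write_csv(tibble::tibble(row = seq_along(r$scores), score = r$scores),
                     file.path(outdir, sprintf("oof_scores_%s.csv", m)))
  }
  summary <- tidy.run_report(report)
  summary$seconds <- NULL  # wall-clock timing would break byte-reproducibility
  obj <- list(summary = summary,
              delong = report$delong,
              tpe_scope = report$tpe_scope,
              seed = report$config$seed,
              n_folds = report$config$n_folds)
  jsonlite::write_json(obj, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(outdir)
}

#' Per-index group comparison table
#'
#' Compares the two label groups index by index, the way cohort baseline
#' tables are reported: binary indices (values in {0, 1}) get counts,
#' percentages and Fisher's exact test; continuous indices get mean, SD and
#' the Brunner-Munzel test.  Significance is flagged at 0.05.
#'
#' @param table A `feature_tbl`.
#' @param alpha Significance level for the flag.
#' @return A tibble with one row per index.
#' @export
group_comparison_table <- function(table, alpha = 0.05) {
  if (!inherits(table, "feature_tbl")) abort("`table` must be a feature_tbl.")
  labels <- ft_labels(table)
  if (length(unique(labels)) < 2L) abort("Both groups must be present.")
  vals <- ft_values(table)
  rows <- lapply(colnames(vals), function(nm) {
    v <- vals[, nm]
    g1 <- v[labels == 1L]
    g2 <- v[labels == 2L]
    is_binary <- all(v %in% c(0, 1))
    if (is_binary) {
      tab <- rbind(c(sum(g1 == 1), sum(g1 == 0)), c(sum(g2 == 1), sum(g2 == 0)))
      p <- stats::fisher.test(tab)$p.value
      tibble::tibble(index = nm, kind = "binary",
                     stat_group1 = mean(g1), stat_group2 = mean(g2),
                     spread_group1 = NA_real_, spread_group2 = NA_real_,
                     test = "fisher", p_value = p)
    } else {
      bm <- brunner_munzel(g1, g2)
      tibble::tibble(index = nm, kind = "continuous",
                     stat_group1 = mean(g1), stat_group2 = mean(g2),
                     spread_group1 = stats::sd(g1), spread_group2 = stats::sd(g2),
                     test = "brunner_munzel", p_value = bm$p)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
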