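# ROC analysis, association measures, and the paired/rank tests used to
# compare methods and groups.

# normalize labels to integers 1 (positive) / 2 (negative); numeric 0/1 and
# 1/2 codings keep their conventional positive class, and logical/0-1
# vectors may be constant (a degenerate classifier is still a prediction)
as_binary_labels <- function(labels) {
  if (is.factor(labels)) return(ifelse(as.integer(labels) == 1L, 1L, 2L))
  if (is.logical(labels)) return(ifelse(labels, 1L, 2L))
  u <- sort(unique(labels))
  if (is.numeric(labels) && all(u %in% c(0, 1))) {
    return(ifelse(labels == 1, 1L, 2L))
  }
  if (is.numeric(labels) && all(u %in% c(1, 2))) {
    return(as.integer(labels))
  }
  if (length(u) != 2L) abort("Labels must contain exactly two classes.")
  ifelse(labels == u[1L], 1L, 2L)
}

#' ROC analysis with best-threshold selection
#'
#' Thresholds are the midpoints between consecutive distinct sorted scores,
#' with -Inf/+Inf sentinels; a participant is called positive when the score
#' is at or above the threshold.  The AUC is the pairwise concordance
#' probability (ties counted 0.5), which coincides with the trapezoidal
#' area under the empirical curve.  The reported threshold maximizes
#' sensitivity + specificity, ties broken by higher sensitivity and then by
#' lower threshold.
#'
#' @param scores Numeric scores, larger = more positive (e.g., the posterior
#'   probability of the positive class).
#' @param labels Two-class labels; a factor's first level, `TRUE`, integer 1,
#'   or the lexicographically first value is the positive class.
#' @return A `roc_result`: `points` tibble (threshold, sensitivity,
#'   specificity), `auc`, `best_threshold`, `sens_at_best`, `spec_at_best`.
#' @export
roc_analysis <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (length(scores) != length(lab)) abort("`scores` and `labels` lengths differ.")
  if (anyNA(scores)) abort("`scores` must not contain NA.")
  pos <- scores[lab == 1L]
  neg <- scores[lab == 2L]
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("Both classes must be present for ROC analysis.")
  }
  cmp <- outer(pos, neg, "-")
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)

  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))

  j <- sens + spec
  # ties at the maximum (within float tolerance) break to the highest
  # sensitivity, then the lowest threshold (thresholds ascend)
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[sens[cand] >= max(sens[cand]) - 1e-12]
  best <- cand[1L]

  structure(list(points = tibble::tibble(threshold = thresholds,
                                         sensitivity = sens,
                                         specificity = spec),
                 auc = auc,
                 best_threshold = thresholds[best],
                 sens_at_best = sens[best],
                 spec_at_best = spec[best],
                 n_pos = length(pos),
                 n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (n+ = %d, n- = %d)\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("best threshold %.3g: sensitivity %.3f, specificity %.3f\n",
              x$best_threshold, x$sens_at_best, x$spec_at_best))
  invisible(x)
}

#' Confusion table, Fisher's exact test, and Yule's Q
#'
#' Cross-tabulates predicted against actual class (rows = actual, columns =
#' predicted, positive first), tests the association with the two-sided
#' Fisher exact test (all tables with fixed margins whose probability does
#' not exceed the observed one), and quantifies its strength with Yule's
#' coefficient `Q = (ad - bc)/(ad + bc)`.
#'
#' @param predicted,actual Length-N binary vectors (logical, 0/1 with 1
#'   positive, or two-level labels).
#' @return An `association_result`: `table` (2 x 2 matrix), `fisher_p`,
#'   `yule_q` (NA with `q_defined = FALSE` when `ad + bc = 0`).
#' @export
confusion_and_association <- function(predicted, actual) {
  pl <- as_binary_labels(predicted)
  al <- as_binary_labels(actual)
  if (length(pl) != length(al)) abort("`predicted` and `actual` lengths differ.")
  tab <- matrix(c(sum(al == 1 & pl == 1), sum(al == 1 & pl == 2),
                  sum(al == 2 & pl == 1), sum(al == 2 & pl == 2)),
                nrow = 2, byrow = TRUE,
                dimnames = list(actual = c("positive", "negative"),
                                predicted = c("positive", "negative")))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  fisher_p <- stats::fisher.test(tab)$p.value
  denom <- a * d + b * c_
  q_defined <- denom > 0
  if (!q_defined) warn("Yule's Q undefined: ad + bc = 0.")
  structure(list(table = tab,
                 fisher_p = fisher_p,
                 yule_q = if (q_defined) (a * d - b * c_) / denom else NA_real_,
                 q_defined = q_defined),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher two-sided p = %.4g; Yule's Q = %s\n", x$fisher_p,
              if (x$q_defined) sprintf("%.4f", x$yule_q) else "undefined"))
  invisible(x)
}

# placement values of one score vector: V10 (per positive), V01 (per
# negative), and the AUC
placement_values <- function(scores, lab) {
  pos <- scores[lab == 1L]
  neg <- scores[lab == 2L]
  psi <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Variance of a single AUC by the DeLong structural components
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels (positive first; see [roc_analysis()]).
#' @return The estimated variance of the empirical AUC.
#' @export
delong_auc_variance <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  pv <- placement_values(scores, lab)
  stats::var(pv$v10) / length(pv$v10) + stats::var(pv$v01) / length(pv$v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same participants via
#' the covariance of their placement values; the difference divided by its
#' standard error is referred to the standard normal (two-sided).
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared two-class labels.
#' @return A `delong_result`: `auc_a`, `auc_b`, `z`, `p`, `se`, and
#'   `flagged = TRUE` with `p = 1` when the difference has zero variance
#'   (e.g., identical score vectors).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  lab <- as_binary_labels(labels)
  if (length(scores_a) != length(lab) || length(scores_b) != length(lab)) {
    abort("Scores and labels must have equal length.")
  }
  pa <- placement_values(scores_a, lab)
  pb <- placement_values(scores_b, lab)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  flagged <- var_diff <= 0
  if (flagged) {
    warn("Zero variance of the AUC difference; p set to 1 by convention.")
    z <- 0
    p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p,
                 se = sqrt(max(var_diff, 0)), flagged = flagged),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC %.3f vs %.3f: z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$z, x$p, if (x$flagged) " (degenerate)" else ""))
  invisible(x)
}

#' Holm step-down adjustment
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1) in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must be numbers in [0, 1].")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Brunner-Munzel test
#'
#' Rank-based two-sample test of the relative effect
#' `p = P(A < B) + 0.5 P(A = B)` estimated from midranks, with the
#' studentized statistic and Welch-type degrees of freedom; the two-sided
#' p-value comes from the t distribution.  Robust to unequal variances.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return A `bm_result`: `statistic`, `df`, `p`, `relative_effect`, and
#'   `flagged = TRUE` (with NA statistic) when all values are tied so the
#'   rank variance vanishes.
#' @export
brunner_munzel <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (n1 < 2L || n2 < 2L) abort("Each sample needs at least 2 values.")
  n <- n1 + n2
  r <- rank(c(a, b))
  r1 <- rank(a)
  r2 <- rank(b)
  m1 <- mean(r[seq_len(n1)])
  m2 <- mean(r[n1 + seq_len(n2)])
  p_hat <- (m2 - (n2 + 1) / 2) / n1
  v1 <- sum((r[seq_len(n1)] - r1 - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r[n1 + seq_len(n2)] - r2 - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  pooled <- n1 * v1 + n2 * v2
  if (pooled <= 0) {
    warn("All values tied; Brunner-Munzel statistic undefined.")
    return(structure(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                          relative_effect = p_hat, flagged = TRUE),
                     class = "bm_result"))
  }
  statistic <- n1 * n2 * (m2 - m1) / (n * sqrt(pooled))
  df <- pooled^2 / ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(statistic), df)
  structure(list(statistic = statistic, df = df, p = p,
                 relative_effect = p_hat, flagged = FALSE),
            class = "bm_result")
}

#' @export
print.bm_result <- function(x, ...) {
  cat(sprintf("<bm_result> relative effect %.3f, W = %s, p = %s\n",
              x$relative_effect,
              if (x$flagged) "NA" else sprintf("%.3f", x$statistic),
              if (x$flagged) "NA" else sprintf("%.4g", x$p)))
  invisible(x)
}
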