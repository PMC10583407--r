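# Synthetic data generators: a cohort emulator drawing each clinical index
# from published per-group summary statistics, and a sparse-signal harness
# with known informative indices for testing the selection methods.

#' Bundled cohort specification
#'
#' The packaged per-index parameter table for the 65-index, two-group
#' (41 drivable / 14 undrivable) post-stroke cohort structure: continuous
#' indices carry per-group means and SDs, binary indices per-group
#' proportions.  Three motor-recovery sub-scores whose group summaries were
#' not published are filled with realistic Brunnstrom-stage values and
#' marked `synthetic` in the `source` column.
#'
#' @return A `cohort_spec` tibble with attribute `n_per_group`
#'   (drivable = 41, undrivable = 14).
#' @export
bundled_cohort_spec <- function() {
  path <- system.file("extdata", "cohort_spec.csv", package = "sparsellgmn",
                      mustWork = TRUE)
  spec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort_spec(spec)
  structure(spec, n_per_group = c(drivable = 41L, undrivable = 14L),
            class = c("cohort_spec", class(spec)))
}

validate_cohort_spec <- function(spec) {
  needed <- c("index", "kind", "mean_drivable", "sd_drivable",
              "mean_undrivable", "sd_undrivable", "prop_drivable",
              "prop_undrivable")
  if (!all(needed %in% names(spec))) {
    abort(sprintf("Cohort spec must have columns: %s.", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(spec$index)) abort("Cohort spec index names must be unique.")
  if (!all(spec$kind %in% c("continuous", "binary"))) {
    abort("Cohort spec `kind` must be 'continuous' or 'binary'.")
  }
  cont <- spec$kind == "continuous"
  if (any(spec$sd_drivable[cont] < 0, na.rm = TRUE) ||
      any(spec$sd_undrivable[cont] < 0, na.rm = TRUE)) {
    abort("SDs must be non-negative.")
  }
  bin <- !cont
  props <- c(spec$prop_drivable[bin], spec$prop_undrivable[bin])
  if (any(props < 0 | props > 1, na.rm = TRUE)) {
    abort("Proportions must lie in [0, 1].")
  }
  invisible(spec)
}

#' Generate a synthetic cohort table
#'
#' Draws a participant-by-index table from a cohort specification:
#' continuous indices are Normal with the per-group mean and SD, binary
#' indices Bernoulli with the per-group proportion, and labels are set by
#' group membership only.  Optionally, continuous indices sharing a block
#' id are equicorrelated within each participant through a shared Gaussian
#' factor with correlation `rho`.
#'
#' @param spec A `cohort_spec` tibble (see [bundled_cohort_spec()]); an
#'   optional `block` column groups indices for equicorrelation.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param n_per_group Named or ordered pair (drivable, undrivable);
#'   defaults to the spec's attribute, or (41, 14).
#' @param rho Within-block equicorrelation in [0, 1) for continuous
#'   indices; 0 (independent draws) by default since index covariances are
#'   not part of the specification.
#' @return An unstandardized `feature_tbl` with label column `aptitude`
#'   (positive class `drivable`).
#' @export
generate_cohort <- function(spec, seed = 1L, n_per_group = NULL, rho = 0) {
  validate_cohort_spec(spec)
  if (is.null(n_per_group)) {
    n_per_group <- attr(spec, "n_per_group") %||% c(drivable = 41L, undrivable = 14L)
  }
  n1 <- as.integer(n_per_group[[1]])
  n2 <- as.integer(n_per_group[[2]])
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  n <- n1 + n2
  group <- rep(c("drivable", "undrivable"), c(n1, n2))
  blocks <- if ("block" %in% names(spec)) spec$block else rep(NA_character_, nrow(spec))

  vals <- matrix(0, nrow = n, ncol = nrow(spec),
                 dimnames = list(NULL, spec$index))
  with_seed(seed, {
    shared <- list()
    if (rho > 0) {
      for (bl in unique(stats::na.omit(blocks))) shared[[bl]] <- rnorm(n)
    }
    for (j in seq_len(nrow(spec))) {
      row <- spec[j, ]
      if (row$kind == "binary") {
        p <- ifelse(group == "drivable", row$prop_drivable, row$prop_undrivable)
        vals[, j] <- rbinom(n, 1L, p)
      } else {
        mu <- ifelse(group == "drivable", row$mean_drivable, row$mean_undrivable)
        sigma <- ifelse(group == "drivable", row$sd_drivable, row$sd_undrivable)
        z <- if (rho > 0 && !is.na(blocks[j])) {
          sqrt(rho) * shared[[blocks[j]]] + sqrt(1 - rho) * rnorm(n)
        } else {
          rnorm(n)
        }
        vals[, j] <- mu + sigma * z
      }
    }
  })
  dat <- tibble::as_tibble(vals)
  dat$aptitude <- group
  feature_table(dat, label_col = "aptitude", positive_class = "drivable")
}

#' Generate sparse-signal data with known informative indices
#'
#' A ground-truth harness for the selection methods: `k` informative
#' indices carry a standardized between-class mean difference `d` (classes
#' at -d/2 and +d/2 on the positive class, unit SD), the remaining columns
#' are pure noise, optionally equicorrelated with coefficient `rho`.
#' Which columns are informative is drawn (seeded) and returned as the
#' recovery truth.
#'
#' @param n Total participants.
#' @param p Number of indices.
#' @param k Number of informative indices, `k <= p`.
#' @param d Standardized mean difference of informative indices (>= 0).
#' @param class_ratio Fraction of positive-class participants.
#' @param rho Equicorrelation among the noise indices, in [0, 1).
#' @param seed Integer seed.
#' @return A list with `table` (a `feature_tbl`, labels `pos`/`neg`,
#'   positive class `pos`) and `truth` (the informative index names).
#' @export
generate_sparse_signal <- function(n = 200L, p = 30L, k = 5L, d = 1.5,
                                   class_ratio = 0.5, rho = 0, seed = 1L) {
  if (k > p) abort("`k` must not exceed `p`.")
  if (d < 0) abort("`d` must be >= 0.")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  n1 <- max(1L, round(n * class_ratio))
  n2 <- n - n1
  if (n2 < 1L) abort("Both classes need at least one participant.")
  labels <- rep(c("pos", "neg"), c(n1, n2))
  names_p <- sprintf("idx%02d", seq_len(p))
  vals <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, names_p))
  with_seed(seed, {
    informative <- sort(sample.int(p, k))
    shift <- ifelse(labels == "pos", d / 2, -d / 2)
    shared <- rnorm(n)
    for (j in seq_len(p)) {
      noise <- if (rho > 0 && !(j %in% informative)) {
        sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)
      } else {
        rnorm(n)
      }
      vals[, j] <- noise + if (j %in% informative) shift else 0
    }
    truth <- names_p[informative]
  })
  dat <- tibble::as_tibble(vals)
  dat$label <- labels
  list(table = feature_table(dat, label_col = "label", positive_class = "pos"),
       truth = truth)
}
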