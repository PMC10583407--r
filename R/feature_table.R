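#' Build a participant-by-index feature table
#'
#' A feature table is the universal input of the package: one row per
#' participant, one numeric column per clinical index, plus a label column
#' with exactly two classes.  The positive class (class 1, conventionally
#' "drivable") is the class whose posterior probability is used as the ROC
#' score throughout.
#'
#' @param data A data frame with one label column and numeric index columns.
#' @param label_col Name of the label column.  Default `"label"`.
#' @param positive_class Which label value is the positive class (mapped to
#'   class 1).  Defaults to the lexicographically first value, so the mapping
#'   is deterministic when left unset.
#' @return A `feature_tbl`: a tibble whose first column is the label factor
#'   (positive level first) followed by the index columns, carrying
#'   standardization state as attributes.
#' @export
feature_table <- function(data, label_col = "label", positive_class = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!label_col %in% names(data)) {
    abort(sprintf("Label column '%s' not found.", label_col))
  }
  dup <- names(data)[duplicated(names(data))]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate index names: %s.", paste(unique(dup), collapse = ", ")))
  }
  lab_raw <- as.character(data[[label_col]])
  lev <- sort(unique(lab_raw))
  if (length(lev) != 2L) {
    abort(sprintf("Label column must have exactly 2 distinct values, found %d.",
                  length(lev)))
  }
  if (is.null(positive_class)) positive_class <- lev[1L]
  positive_class <- as.character(positive_class)
  if (!positive_class %in% lev) {
    abort(sprintf("`positive_class` '%s' is not a label value.", positive_class))
  }
  lab <- factor(lab_raw, levels = c(positive_class, setdiff(lev, positive_class)))

  idx <- data[setdiff(names(data), label_col)]
  if (ncol(idx) < 1L) abort("At least one index column is required.")
  not_num <- names(idx)[!vapply(idx, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(sprintf("Non-numeric index column(s): %s.", paste(not_num, collapse = ", ")))
  }
  if (anyNA(idx) || anyNA(lab)) {
    abort("Missing values are not supported; impute or drop rows first.")
  }

  out <- tibble::as_tibble(c(stats::setNames(list(lab), label_col), as.list(idx)))
  new_feature_tbl(out, label_col, standardized = FALSE, std_params = NULL)
}

new_feature_tbl <- function(data, label_col, standardized, std_params) {
  structure(data,
            label_col = label_col,
            standardized = standardized,
            std_params = std_params,
            class = c("feature_tbl", class(tibble::as_tibble(data))))
}

#' @export
print.feature_tbl <- function(x, ...) {
  cat(sprintf("<feature_tbl> %d participants x %d indices (%s)\n",
              nrow(x), length(ft_index_names(x)),
              if (isTRUE(attr(x, "standardized"))) "standardized" else "raw"))
  cat(sprintf("labels: %s (positive = %s)\n",
              paste(levels(ft_label_factor(x)), collapse = " / "),
              levels(ft_label_factor(x))[1L]))
  NextMethod()
}

ft_label_col <- function(x) attr(x, "label_col")
ft_label_factor <- function(x) x[[ft_label_col(x)]]

#' Accessors for feature tables
#'
#' `ft_labels()` returns integer class labels (1 = positive class,
#' 2 = negative class); `ft_values()` the numeric index matrix;
#' `ft_index_names()` the index names; `ft_targets()` the one-of-C
#' target matrix used by the training code.
#'
#' @param x A `feature_tbl`.
#' @return See the individual descriptions.
#' @export
ft_labels <- function(x) as.integer(ft_label_factor(x))

#' @rdname ft_labels
#' @export
ft_values <- function(x) {
  as.matrix(x[setdiff(names(x), ft_label_col(x))])
}

#' @rdname ft_labels
#' @export
ft_index_names <- function(x) setdiff(names(x), ft_label_col(x))

#' @rdname ft_labels
#' @export
ft_targets <- function(x) {
  lab <- ft_labels(x)
  t_mat <- matrix(0, nrow = length(lab), ncol = 2L)
  t_mat[cbind(seq_along(lab), lab)] <- 1
  t_mat
}

ft_is_standardized <- function(x) isTRUE(attr(x, "standardized"))

ft_std_params <- function(x) attr(x, "std_params")

# rebuild a feature_tbl from parts (used by subsetting helpers)
ft_replace_values <- function(x, values) {
  lab_col <- ft_label_col(x)
  out <- tibble::as_tibble(cbind(stats::setNames(tibble::tibble(ft_label_factor(x)), lab_col),
                                 tibble::as_tibble(values)))
  new_feature_tbl(out, lab_col, attr(x, "standardized"), attr(x, "std_params"))
}

# restrict to a subset of index columns (order given by `indices`)
ft_subset_indices <- function(x, indices) {
  missing_idx <- setdiff(indices, ft_index_names(x))
  if (length(missing_idx) > 0) {
    abort(sprintf("Unknown index name(s): %s.", paste(missing_idx, collapse = ", ")))
  }
  vals <- ft_values(x)[, indices, drop = FALSE]
  params <- ft_std_params(x)
  if (!is.null(params)) params <- params[match(indices, params$index), , drop = FALSE]
  out <- ft_replace_values(x, vals)
  attr(out, "std_params") <- params
  out
}

# restrict to a subset of rows, keeping attributes
ft_subset_rows <- function(x, rows) {
  vals <- ft_values(x)[rows, , drop = FALSE]
  lab_col <- ft_label_col(x)
  out <- tibble::as_tibble(cbind(stats::setNames(tibble::tibble(ft_label_factor(x)[rows]), lab_col),
                                 tibble::as_tibble(vals)))
  new_feature_tbl(out, lab_col, attr(x, "standardized"), attr(x, "std_params"))
}

#' Read a participant feature table from CSV
#'
#' The CSV must have a header row; one column holds the two-class label and
#' every other column is a numeric index.
#'
#' @param path Path to a CSV file.
#' @param label_col Name of the label column.
#' @param positive_class Optional positive-class label value (see
#'   [feature_table()]).
#' @return A `feature_tbl`.
#' @export
read_feature_table <- function(path, label_col = "label", positive_class = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- strsplit(readr::read_lines(path, n_max = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header)) {
    abort(sprintf("Duplicate column names in %s: %s.", path,
                  paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal",
                         col_types = readr::cols(.default = "c"))
  for (nm in setdiff(names(dat), label_col)) {
    # base strtod keeps the round trip bit-exact (fast float parsers can be
    # one ulp off)
    parsed <- suppressWarnings(as.numeric(dat[[nm]]))
    if (anyNA(parsed) && !all(is.na(dat[[nm]]) == is.na(parsed))) {
      abort(sprintf("Non-numeric value(s) in index column '%s'.", nm))
    }
    dat[[nm]] <- parsed
  }
  feature_table(dat, label_col = label_col, positive_class = positive_class)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: round-tripping reproduces the numeric
#' values exactly (full precision is written).
#'
#' @param x A `feature_tbl`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  out <- tibble::as_tibble(x)
  # 17 significant digits guarantee a bit-exact numeric round trip
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                          ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Standardize every index column
#'
#' Each index is transformed to `(x - mean) / sd` using its own sample mean
#' and sample standard deviation (n - 1 denominator).  The parameters are
#' stored on the result so held-out data can be transformed with
#' [apply_standardization()] without leaking validation information.
#'
#' @param x An unstandardized `feature_tbl` with no constant columns.
#' @param zero_sd What to do with a constant (zero-SD) column: `"error"`
#'   (default, names the column) or `"center"` (record sd = 1, so the
#'   column is centered but not scaled).  The centering policy is what the
#'   cross-validation internals use, where a rare binary index can be
#'   constant within a training fold.
#' @return A standardized `feature_tbl` carrying the `(mean, sd)` pairs.
#' @export
standardize <- function(x, zero_sd = c("error", "center")) {
  zero_sd <- match.arg(zero_sd)
  if (!inherits(x, "feature_tbl")) abort("`x` must be a feature_tbl.")
  if (ft_is_standardized(x)) abort("Table is already standardized.")
  vals <- ft_values(x)
  mu <- colMeans(vals)
  sigma <- apply(vals, 2, stats::sd)
  if (any(sigma == 0)) {
    if (zero_sd == "error") {
      abort(sprintf("Constant column(s) cannot be standardized: %s.",
                    paste(colnames(vals)[sigma == 0], collapse = ", ")))
    }
    sigma[sigma == 0] <- 1
  }
  params <- tibble::tibble(index = colnames(vals), mean = unname(mu), sd = unname(sigma))
  apply_standardization(x, params)
}

#' Apply stored standardization parameters
#'
#' Transforms a table with `(mean, sd)` pairs learned elsewhere (typically on
#' a training fold), the leakage-free way to standardize held-out rows.
#'
#' @param x A `feature_tbl`.
#' @param params A tibble with columns `index`, `mean`, `sd` covering every
#'   index column of `x`.
#' @return A standardized `feature_tbl`.
#' @export
apply_standardization <- function(x, params) {
  if (!inherits(x, "feature_tbl")) abort("`x` must be a feature_tbl.")
  idx <- ft_index_names(x)
  if (!all(c("index", "mean", "sd") %in% names(params))) {
    abort("`params` needs columns index, mean, sd.")
  }
  if (length(idx) != nrow(params) || !setequal(params$index, idx)) {
    abort("`params` must cover exactly the index columns of `x`.")
  }
  params <- params[match(idx, params$index), , drop = FALSE]
  vals <- sweep(sweep(ft_values(x), 2, params$mean, "-"), 2, params$sd, "/")
  out <- ft_replace_values(x, vals)
  attr(out, "standardized") <- TRUE
  attr(out, "std_params") <- params
  out
}

#' Invert a standardization
#'
#' Maps a standardized table back to the original scale using its stored
#' parameters.
#'
#' @param x A standardized `feature_tbl`.
#' @return The table on the original scale.
#' @export
unstandardize <- function(x) {
  if (!ft_is_standardized(x)) abort("Table is not standardized.")
  params <- ft_std_params(x)
  vals <- sweep(sweep(ft_values(x), 2, params$sd, "*"), 2, params$mean, "+")
  out <- ft_replace_values(x, vals)
  attr(out, "standardized") <- FALSE
  attr(out, "std_params") <- NULL
  out
}

#' Analysis configuration
#'
#' Bundles every tunable of the training and evaluation pipeline with the
#' study defaults: stochastic gradient descent with learning rate 0.01 and
#' batch size 50 for up to 10,000 epochs, early stopping once the epoch loss
#' fails to improve by more than 1e-4 for more than 5 consecutive epochs,
#' a single mixture component per class, and 11-fold cross-validation.
#'
#' @param learning_rate SGD learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_min_delta Minimum epoch-loss improvement that resets the
#'   early-stopping counter.
#' @param early_stop_patience Consecutive non-improving epochs tolerated
#'   before stopping.
#' @param lambda L1 regularization coefficient for the reduction layer:
#'   a non-negative number, or `"tpe"` to tune it with
#'   [tune_lambda_tpe()].
#' @param n_components Gaussian components per class (M).
#' @param n_folds Cross-validation folds (K).
#' @param seed Integer seed for every stochastic step.
#' @param feature_subset Optional character vector restricting the analysis
#'   to named indices.
#' @param tpe List of tree-structured Parzen estimator settings:
#'   `low`, `high` (log-uniform search range), `n_trials`, `inner_folds`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(learning_rate = 0.01,
                            batch_size = 50L,
                            max_epochs = 10000L,
                            early_stop_min_delta = 1e-4,
                            early_stop_patience = 5L,
                            lambda = "tpe",
                            n_components = 1L,
                            n_folds = 11L,
                            seed = 1L,
                            feature_subset = NULL,
                            tpe = list()) {
  stopifnot_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  stopifnot_scalar_number(batch_size, "batch_size", positive = TRUE)
  stopifnot_scalar_number(max_epochs, "max_epochs")
  if (max_epochs < 0) abort("`max_epochs` must be >= 0.")
  stopifnot_scalar_number(early_stop_min_delta, "early_stop_min_delta", positive = TRUE)
  stopifnot_scalar_number(early_stop_patience, "early_stop_patience", positive = TRUE)
  if (!identical(lambda, "tpe")) {
    stopifnot_scalar_number(lambda, "lambda")
    if (lambda < 0) abort("`lambda` must be >= 0.")
  }
  stopifnot_scalar_number(n_components, "n_components", positive = TRUE)
  stopifnot_scalar_number(n_folds, "n_folds", positive = TRUE)
  stopifnot_scalar_number(seed, "seed")
  tpe_defaults <- list(low = 1e-5, high = 10, n_trials = 100L, inner_folds = 5L)
  tpe <- utils::modifyList(tpe_defaults, tpe)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_min_delta = early_stop_min_delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 lambda = lambda,
                 n_components = as.integer(n_components),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 feature_subset = feature_subset,
                 tpe = tpe),
            class = "analysis_config")
}
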