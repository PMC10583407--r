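#' Quadratic input expansion of the LLGMN
#'
#' Maps a length-D input to the nonlinear feature vector the log-linearized
#' Gaussian mixture model is linear in: a constant 1, the raw entries, and
#' the upper-triangular pairwise products `x_i * x_j` (i <= j, row-major),
#' giving `H = 1 + D + D(D+1)/2` entries.
#'
#' @param x Numeric vector with finite entries.
#' @return The length-H expanded vector.
#' @export
expand_input <- function(x) {
  if (!is.numeric(x) || length(x) < 1L) abort("`x` must be a numeric vector.")
  if (any(!is.finite(x))) abort("`x` must have finite entries.")
  drop(cpp_expand(matrix(as.double(x), nrow = 1L)))
}

new_llgmn <- function(weights, n_components, index_names, loss = NA_real_,
                      epochs = 0L, trace = numeric(), config = NULL) {
  structure(list(weights = weights,
                 n_classes = 2L,
                 n_components = as.integer(n_components),
                 index_names = index_names,
                 loss = loss,
                 epochs = epochs,
                 trace = trace,
                 config = config),
            class = "llgmn")
}

#' @export
print.llgmn <- function(x, ...) {
  cat(sprintf("<llgmn> D = %d indices, M = %d component(s), %d weights\n",
              length(x$index_names), x$n_components, length(x$weights)))
  if (is.finite(x$loss)) {
    cat(sprintf("training cross-entropy %.6g after %d epoch(s)\n", x$loss, x$epochs))
  }
  invisible(x)
}

expected_h <- function(d) 1L + d + (d * (d + 1L)) %/% 2L

#' Forward pass of a log-linearized Gaussian mixture network
#'
#' Computes the softmax over the C*M component units (with max-subtraction
#' for overflow safety) and sums the units of each class into the class
#' posterior probabilities.
#'
#' @param model An `llgmn` model.
#' @param x A length-D input vector (not yet expanded), or an N x D matrix.
#' @return For a vector input, a list with `posterior` (length C, sums to 1)
#'   and `units` (length C*M); for a matrix, the same with one row per input.
#' @export
llgmn_forward <- function(model, x) {
  if (is.vector(x)) {
    d <- length(model$index_names)
    if (length(x) != d) {
      abort(sprintf("Input has length %d but the model expects %d.", length(x), d))
    }
    fw <- cpp_forward(cpp_expand(matrix(as.double(x), nrow = 1L)),
                      model$weights, model$n_components)
    list(posterior = drop(fw$posterior), units = drop(fw$units))
  } else {
    if (ncol(x) != length(model$index_names)) {
      abort(sprintf("Input has %d columns but the model expects %d.",
                    ncol(x), length(model$index_names)))
    }
    cpp_forward(cpp_expand(as.matrix(x)), model$weights, model$n_components)
  }
}

#' Construct an LLGMN from explicit Gaussian mixture parameters
#'
#' Log-linearizes a C-class Gaussian mixture classifier: the resulting
#' network's forward posteriors equal the Bayes posteriors of the mixture
#' evaluated directly.  Used as a bridge between generative parameters and
#' the discriminative network, and as an oracle in tests.
#'
#' @param priors C x M matrix of component priors, summing to 1 overall.
#' @param means C x M x D array of component means.
#' @param covariances C x M x D x D array of symmetric positive-definite
#'   component covariances.
#' @return An `llgmn` whose forward pass reproduces the mixture posteriors.
#' @export
log_linearize_gmm <- function(priors, means, covariances) {
  priors <- as.matrix(priors)
  c_n <- nrow(priors)
  m_n <- ncol(priors)
  if (abs(sum(priors) - 1) > 1e-8) abort("`priors` must sum to 1.")
  dims <- dim(means)
  if (length(dims) != 3L || dims[1] != c_n || dims[2] != m_n) {
    abort("`means` must be a C x M x D array.")
  }
  d <- dims[3]
  h <- expected_h(d)
  w_mat <- matrix(0, nrow = h, ncol = c_n * m_n)
  pair_i <- unlist(lapply(seq_len(d), function(i) rep(i, d - i + 1L)))
  pair_j <- unlist(lapply(seq_len(d), function(i) i:d))
  for (cc in seq_len(c_n)) {
    for (mm in seq_len(m_n)) {
      mu <- as.numeric(means[cc, mm, ])
      sigma <- matrix(covariances[cc, mm, , ], nrow = d)
      ch <- tryCatch(chol(sigma), error = function(e) {
        abort(sprintf("Covariance of class %d component %d is not positive definite.", cc, mm))
      })
      a_mat <- chol2inv(ch)
      log_det <- 2 * sum(log(diag(ch)))
      col <- (cc - 1L) * m_n + mm
      b0 <- log(priors[cc, mm]) - 0.5 * d * log(2 * pi) - 0.5 * log_det -
        0.5 * drop(t(mu) %*% a_mat %*% mu)
      lin <- drop(a_mat %*% mu)
      quad <- ifelse(pair_i == pair_j,
                     -0.5 * a_mat[cbind(pair_i, pair_j)],
                     -a_mat[cbind(pair_i, pair_j)])
      w_mat[, col] <- c(b0, lin, quad)
    }
  }
  # pin the anchor unit at zero; softmax is invariant to a shared shift
  w_mat <- w_mat - w_mat[, ncol(w_mat)]
  new_llgmn(w_mat, m_n, paste0("x", seq_len(d)))
}

#' Cross-entropy of a model on a feature table
#'
#' The summed (not averaged) cross-entropy error
#' `-sum_n sum_c t_nc ln p(c | x_n)`, with posteriors clipped below at 1e-12
#' before the logarithm.  This is the accuracy measure used for training,
#' early stopping, permutation importance, and the partial-KLI score.
#'
#' @param model An `llgmn` or `sparse_llgmn` model.
#' @param table A `feature_tbl` whose index columns match the model.
#' @return The scalar cross-entropy.
#' @export
cross_entropy <- function(model, table) {
  post <- posterior_matrix(model, table)
  -sum(ft_targets(table) * log(pmax(post, 1e-12)))
}

# N x 2 posterior matrix of either model class on a feature table
posterior_matrix <- function(model, table) {
  vals <- ft_values(table)
  if (!identical(colnames(vals), model$index_names)) {
    if (!setequal(colnames(vals), model$index_names)) {
      abort("Table indices do not match the model's indices.")
    }
    vals <- vals[, model$index_names, drop = FALSE]
  }
  if (inherits(model, "sparse_llgmn")) {
    vals <- sweep(vals, 2, model$w, "*")
  }
  cpp_forward(cpp_expand(vals), model$weights, model$n_components)$posterior
}

#' Analytic gradient of the cross-entropy
#'
#' Backpropagated gradient of [cross_entropy()] with respect to the LLGMN
#' weight matrix; the anchored final column is forced to zero.
#'
#' @param model An `llgmn` model.
#' @param table A `feature_tbl` batch.
#' @return An H x (C*M) gradient matrix.
#' @export
llgmn_gradient <- function(model, table) {
  if (nrow(table) < 1L) abort("`table` must be non-empty.")
  vals <- ft_values(table)[, model$index_names, drop = FALSE]
  cpp_gradient(cpp_expand(vals), model$weights, model$n_components,
               ft_targets(table))
}

check_trainable <- function(table) {
  if (!inherits(table, "feature_tbl")) abort("`table` must be a feature_tbl.")
  if (!ft_is_standardized(table)) {
    abort("Training expects a standardized table; call standardize() first.")
  }
  if (length(unique(ft_labels(table))) < 2L) {
    abort("Training data must contain both classes.")
  }
}

#' Train a plain LLGMN by mini-batch SGD
#'
#' Minimizes the summed cross-entropy by stochastic gradient descent with the
#' configured learning rate and batch size, reshuffling every epoch with a
#' seeded generator.  Training stops at `max_epochs` or once the full-data
#' epoch loss fails to improve by more than `early_stop_min_delta` for more
#' than `early_stop_patience` consecutive epochs; the best-loss weights are
#' returned.  Weights start at zero, so the initial posterior is uniform.
#'
#' @param table A standardized `feature_tbl` with both classes present.
#' @param config An [analysis_config()].
#' @return A trained `llgmn`.
#' @export
train_llgmn <- function(table, config = analysis_config()) {
  check_trainable(table)
  vals <- ft_values(table)
  fit <- cpp_train(vals, ft_targets(table), config$n_components,
                   FALSE, rep(1, ncol(vals)), 0,
                   config$learning_rate, config$batch_size,
                   config$max_epochs, config$early_stop_min_delta,
                   config$early_stop_patience, config$seed)
  new_llgmn(fit$W, config$n_components, colnames(vals),
            loss = fit$loss, epochs = fit$epochs, trace = fit$trace,
            config = config)
}

#' @export
predict.llgmn <- function(object, newdata, ...) {
  post <- posterior_matrix(object, newdata)
  tibble::tibble(p_class1 = post[, 1], p_class2 = post[, 2])
}

#' Serialize a model to JSON
#'
#' Writes dimensions, flattened weights (and the reduction gates for sparse
#' models) plus a config echo; [read_model_json()] restores the model.
#'
#' @param model An `llgmn` or `sparse_llgmn`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(type = class(model)[1],
              n_components = model$n_components,
              index_names = model$index_names,
              weights = as.numeric(model$weights),
              weight_dim = dim(model$weights),
              loss = model$loss,
              epochs = model$epochs)
  if (inherits(model, "sparse_llgmn")) {
    obj$w <- as.numeric(model$w)
    obj$lambda <- model$lambda
  }
  if (!is.null(model$config)) obj$config <- unclass(model$config)[
    c("learning_rate", "batch_size", "max_epochs", "early_stop_min_delta",
      "early_stop_patience", "n_components", "n_folds", "seed")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w_mat <- matrix(obj$weights, nrow = obj$weight_dim[1], ncol = obj$weight_dim[2])
  model <- new_llgmn(w_mat, obj$n_components, obj$index_names,
                     loss = obj$loss %||% NA_real_, epochs = obj$epochs %||% 0L)
  if (identical(obj$type, "sparse_llgmn")) {
    model <- new_sparse_llgmn(obj$w, model, obj$lambda)
  }
  model
}
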