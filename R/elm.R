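sigmoid <- function(z) 1 / (1 + exp(-z))

# minimum-norm least squares via the SVD pseudo-inverse
pinv_solve <- function(h, y, tol = 1e-10) {
  sv <- svd(h)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(rep(0, ncol(h)))
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
}

scale_features <- function(x, lo, hi) {
  rng <- hi - lo
  out <- sweep(sweep(x, 2, lo), 2, ifelse(rng == 0, 1, rng), "/") * 2 - 1
  # degenerate (zero-range) features are passed through at 0
  out[, rng == 0] <- 0
  out
}

#' Fit an extreme learning machine (ELM) regression
#'
#' A single-hidden-layer network whose input weights `W` and biases `b`
#' are drawn once, uniformly on \[-1, 1\], from the seeded stream and then
#' fixed; only the output weights `beta` are solved, by minimum-norm least
#' squares on the realized hidden-layer matrix
#' `H = sigmoid(X_scaled %*% t(W) + b)`. Inputs are min-max scaled to
#' \[-1, 1\] per feature (training ranges are stored in the model) so the
#' sigmoid is not saturated by raw absorbance magnitudes.
#'
#' @param x predictor matrix (selected wavenumbers).
#' @param y dose vector (mg/g).
#' @param n_hidden number of hidden nodes (>= 1).
#' @param seed integer seed for the hidden-layer draw.
#' @return an object of class `elm_fit`.
#' @export
fit_elm <- function(x, y, n_hidden, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (n_hidden < 1) rlang::abort("`n_hidden` must be >= 1.")
  if (nrow(x) < 2 || nrow(x) != length(y)) {
    rlang::abort("`x` needs >= 2 rows matching `length(y)`.")
  }
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  if (any(hi - lo == 0)) {
    rlang::warn("Zero-range feature(s) passed through at 0.")
  }
  xs <- scale_features(x, lo, hi)
  set.seed(seed)
  w <- matrix(stats::runif(n_hidden * ncol(x), -1, 1), n_hidden, ncol(x))
  b <- stats::runif(n_hidden, -1, 1)
  h <- sigmoid(tcrossprod(xs, w) + rep(b, each = nrow(xs)))
  beta <- drop(pinv_solve(h, y))
  structure(list(
    n_hidden = as.integer(n_hidden),
    input_weights = w, biases = b, output_weights = beta,
    activation = "sigmoid",
    scale_min = lo, scale_max = hi,
    seed = as.integer(seed),
    fitted = drop(h %*% beta)
  ), class = "elm_fit")
}

#' Predict doses from a fitted ELM
#'
#' @param object an `elm_fit`.
#' @param newdata matrix with the training number of features.
#' @param ... unused.
#' @return predicted dose vector `sigmoid(scale(X) W' + b) beta`.
#' @export
predict.elm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$input_weights)) {
    rlang::abort(sprintf(
      "Model was trained on %d features but `newdata` has %d.",
      ncol(object$input_weights), ncol(newdata)
    ))
  }
  xs <- scale_features(newdata, object$scale_min, object$scale_max)
  h <- sigmoid(tcrossprod(xs, object$input_weights) +
                 rep(object$biases, each = nrow(xs)))
  drop(h %*% object$output_weights)
}

#' @export
print.elm_fit <- function(x, ...) {
  cat(sprintf("ELM regression: %d hidden node(s), %d input feature(s), sigmoid activation\n",
              x$n_hidden, ncol(x$input_weights)))
  invisible(x)
}

#' @export
glance.elm_fit <- function(x, ...) {
  tibble::tibble(n_hidden = x$n_hidden,
                 n_features = ncol(x$input_weights),
                 seed = x$seed)
}

#' Sweep the ELM hidden-node count by leave-one-out cross-validation
#'
#' For each node count the hidden layer is redrawn per fit from the seeded
#' stream and the model scored by LOO RMSECV on the calibration data only
#' (prediction-set peeking is structurally impossible: the function never
#' sees prediction samples). The best count minimizes RMSECV; ties go to
#' fewer nodes.
#'
#' @param x calibration predictor matrix.
#' @param y calibration dose vector.
#' @param node_range integer vector of hidden-node counts to try
#'   (default 1:80).
#' @param seed integer master seed; per-fit seeds are derived from it.
#' @return a list with `best_n_hidden`, `rmsecv` (tibble: n_hidden,
#'   rmsecv, r_cv) and `predictions` (out-of-fold, at the best count).
#' @export
elm_sweep <- function(x, y, node_range = 1:80, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(node_range) == 0) rlang::abort("`node_range` must be nonempty.")
  if (any(node_range >= n - 1)) {
    rlang::warn("Node count(s) at or above the fold size: interpolation regime.")
  }
  set.seed(seed)
  fit_seeds <- matrix(
    sample.int(2147483646L, length(node_range) * n, replace = TRUE),
    nrow = length(node_range)
  )
  preds <- matrix(NA_real_, n, length(node_range))
  for (k in seq_along(node_range)) {
    for (i in seq_len(n)) {
      fit <- suppressWarnings(
        fit_elm(x[-i, , drop = FALSE], y[-i], node_range[k],
                seed = fit_seeds[k, i])
      )
      preds[i, k] <- predict(fit, x[i, , drop = FALSE])
    }
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  r_cv <- apply(preds, 2, function(p) stats::cor(y, p))
  best <- which.min(rmsecv)
  list(
    best_n_hidden = as.integer(node_range[best]),
    rmsecv = tibble::tibble(n_hidden = as.integer(node_range),
                            rmsecv = rmsecv, r_cv = r_cv),
    rmsecv_min = rmsecv[best],
    r_cv = r_cv[best],
    predictions = preds[, best]
  )
}
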