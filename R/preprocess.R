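#' Trim noisy band edges off a spectra table
#'
#' Drops the first `n_front` and last `n_back` grid points (and the
#' corresponding columns), the positional-deletion convention used when
#' the instrument's band edges are dominated by noise. With the default
#' raw grid of [synthetic_config()], `trim_spectra(data, 500, 400)` leaves
#' exactly 2800 variables.
#'
#' @param data a spectra tibble.
#' @param n_front,n_back number of points to delete at each end.
#' @return the trimmed spectra tibble; grid and matrix stay aligned.
#' @export
trim_spectra <- function(data, n_front = 500, n_back = 400) {
  check_spectra(data)
  cols <- spectra_cols(data)
  p <- length(cols)
  if (n_front < 0 || n_back < 0) rlang::abort("Trim counts must be >= 0.")
  if (n_front + n_back >= p) {
    rlang::abort(sprintf(
      "Cannot trim %d + %d points from %d variables.", n_front, n_back, p
    ))
  }
  keep <- cols[(n_front + 1):(p - n_back)]
  data[c("dose", "set", keep)]
}

#' Per-spectrum preprocessing treatments
#'
#' `smooth_ma()` is a centered moving average whose window shrinks
#' symmetrically at the edges; `normalize_max()` divides a spectrum by its
#' maximum so the apex becomes 1 (the common IR convention);
#' `normalize_length()` is the unit-Euclidean-length variant;
#' `snv()` is the standard normal variate transform
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation,
#' which removes any per-spectrum affine gain/offset distortion exactly:
#' `snv(a + b * x) == snv(x)` for `b > 0`.
#'
#' @param x absorbance vector.
#' @param window odd integer window width >= 3.
#' @return the transformed vector.
#' @export
smooth_ma <- function(x, window = 9) {
  n <- length(x)
  if (window %% 2 == 0) rlang::abort("`window` must be odd.")
  if (window < 3 || window > n) {
    rlang::abort("`window` must be between 3 and length(x).")
  }
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1))
}

#' @rdname smooth_ma
#' @export
normalize_max <- function(x) {
  m <- max(x)
  if (max(abs(x)) == 0) rlang::abort("Cannot normalize an all-zero spectrum.")
  if (m <= 0) rlang::abort("Spectrum maximum must be positive.")
  x / m
}

#' @rdname smooth_ma
#' @export
normalize_length <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) rlang::abort("Cannot normalize an all-zero spectrum.")
  x / nrm
}

#' @rdname smooth_ma
#' @export
snv <- function(x) {
  if (length(x) < 2) rlang::abort("SNV needs at least 2 points.")
  s <- stats::sd(x)
  if (s == 0) rlang::abort("Degenerate spectrum: zero spread, SNV undefined.")
  (x - mean(x)) / s
}

#' Apply a preprocessing method row-wise to a spectra table
#'
#' The four treatments compared in the calibration study: `"raw"`
#' (identity), `"smoothing"` (moving average), `"normalize"`
#' (max-normalization) and `"snv"`. Dose labels and set membership are
#' untouched; sample and variable counts are preserved.
#'
#' @param data a spectra tibble.
#' @param method one of `"raw"`, `"smoothing"`, `"normalize"`, `"snv"`.
#' @param window moving-average window for `"smoothing"`.
#' @return the preprocessed spectra tibble.
#' @export
preprocess_spectra <- function(data,
                               method = c("raw", "smoothing", "normalize", "snv"),
                               window = 9) {
  method <- match.arg(method)
  check_spectra(data)
  if (method == "raw") return(data)
  m <- spectra_matrix(data)
  f <- switch(method,
    smoothing = function(x) smooth_ma(x, window),
    normalize = normalize_max,
    snv = snv
  )
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    out[i, ] <- tryCatch(f(m[i, ]), error = function(e) {
      rlang::abort(sprintf("Preprocessing failed for sample %d: %s",
                           i, conditionMessage(e)))
    })
  }
  as_spectra(spectra_grid(data), out, data$dose, data$set)
}
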