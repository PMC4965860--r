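# Single-response NIPALS engine. For one y the inner NIPALS loop is
# non-iterative: w = E'f up to scale, so each latent variable costs a few
# matrix-vector products plus a rank-1 deflation. Returns weights W,
# x-loadings P, y-loadings q, scores T, and the regression coefficient
# matrix B whose column a gives the coefficients (on centered X) of the
# a-component model, so all nested models come out of one fit.
pls1_engine <- function(x, y, ncomp, strict = TRUE, tol = 1e-12) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  x_mean <- colMeans(x); y_mean <- mean(y)
  e <- sweep(x, 2, x_mean); f <- y - y_mean
  scale0 <- sum(e * e)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)[, 1]
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn <= tol * (1 + sqrt(scale0) * sqrt(sum(f^2)))) break
    w <- w / wn
    t <- (e %*% w)[, 1]
    tt <- sum(t^2)
    if (tt <= tol * max(scale0, 1)) break
    pa <- crossprod(e, t)[, 1] / tt
    qa <- sum(f * t) / tt
    e <- e - tcrossprod(t, pa)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; q[a] <- qa
    a_done <- a
  }
  if (a_done < ncomp && strict) {
    rlang::abort(sprintf(
      "X is rank-deficient beyond %d latent variable(s); request fewer components.",
      a_done
    ))
  }
  ncomp <- max(a_done, 1L)
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  # R = W (P'W)^{-1} built recursively; B[, a] are the a-component coefficients
  R <- matrix(0, p, ncomp); B <- matrix(0, p, ncomp)
  b <- numeric(p)
  for (a in seq_len(ncomp)) {
    r <- W[, a]
    if (a > 1) {
      r <- r - R[, 1:(a - 1), drop = FALSE] %*%
        crossprod(P[, 1:(a - 1), drop = FALSE], W[, a])
    }
    R[, a] <- r
    b <- b + r * q[a]
    B[, a] <- b
  }
  list(n_components = ncomp, x_mean = x_mean, y_mean = y_mean,
       weights = W, x_loadings = P, y_loadings = q, scores = Tm,
       coef_path = B)
}

#' Fit a single-response PLS regression (NIPALS)
#'
#' Latent variables are extracted by NIPALS deflation, maximising the
#' covariance between the projected predictors and the response. X is
#' column-mean-centered but not variance-scaled (the spectroscopy
#' convention; SNV already standardizes rows).
#'
#' @param x predictor matrix (samples by variables).
#' @param y numeric response (dose, mg/g).
#' @param ncomp number of latent variables; must be achievable by the rank
#'   of centered `x`, otherwise an error suggests fewer components.
#' @return an object of class `pls_fit` with the weights, loadings,
#'   scores, centering vectors and the regression coefficient vector on
#'   the original (centered) variables.
#' @seealso [pls_loo()] for component selection, [predict.pls_fit()].
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y) || nrow(x) < 2) {
    rlang::abort("`x` rows and `y` length must match and be >= 2.")
  }
  if (ncomp < 1 || ncomp > min(nrow(x) - 1, ncol(x))) {
    rlang::abort("`ncomp` must be in [1, min(rows - 1, cols)].")
  }
  if (stats::var(y) == 0) {
    # degenerate but well-defined: the model predicts the mean
    fit <- list(n_components = as.integer(ncomp),
                x_mean = colMeans(x), y_mean = mean(y),
                weights = matrix(0, ncol(x), ncomp),
                x_loadings = matrix(0, ncol(x), ncomp),
                y_loadings = rep(0, ncomp),
                scores = matrix(0, nrow(x), ncomp),
                coefficients = rep(0, ncol(x)))
    return(structure(fit, class = "pls_fit"))
  }
  eng <- pls1_engine(x, y, ncomp, strict = TRUE)
  structure(list(
    n_components = eng$n_components,
    x_mean = eng$x_mean, y_mean = eng$y_mean,
    weights = eng$weights, x_loadings = eng$x_loadings,
    y_loadings = eng$y_loadings, scores = eng$scores,
    coefficients = eng$coef_path[, eng$n_components]
  ), class = "pls_fit")
}

#' Predict doses from a fitted PLS model
#'
#' @param object a `pls_fit`.
#' @param newdata matrix with the training number of columns.
#' @param ... unused.
#' @return predicted dose vector: `(X - x_mean) %*% coefficients + y_mean`.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    rlang::abort(sprintf(
      "Model was trained on %d variables but `newdata` has %d.",
      length(object$x_mean), ncol(newdata)
    ))
  }
  drop(sweep(newdata, 2, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS regression: %d latent variable(s), %d variables\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Leave-one-out cross-validation of PLS over component counts
#'
#' For each left-out sample the model is refit on the remainder (all
#' component counts come out of one NIPALS pass) and the sample predicted.
#' The chosen component count minimizes RMSECV; ties go to the smaller
#' count. RMSECV and R_CV are computed from the pooled out-of-fold
#' predictions.
#'
#' @param x predictor matrix.
#' @param y dose vector.
#' @param max_ncomp largest component count to consider; infeasible values
#'   are clipped with a warning.
#' @return a list with `rmsecv` (tibble: ncomp, rmsecv), `ncomp` (chosen),
#'   `r_cv` and `rmsecv_min` at the chosen count, and `predictions`
#'   (pooled out-of-fold, at the chosen count).
#' @export
pls_loo <- function(x, y, max_ncomp = 20) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) rlang::abort("LOO cross-validation needs at least 3 samples.")
  feasible <- min(n - 2, ncol(x))
  if (max_ncomp > feasible) {
    rlang::warn(sprintf("`max_ncomp` clipped from %d to %d.",
                        max_ncomp, feasible))
    max_ncomp <- feasible
  }
  # kernel formulation: each fold's NIPALS runs on the (n-1) x (n-1) Gram
  # matrix instead of the full variable space, which is what makes LOO over
  # thousands of wavenumbers affordable; algebraically identical to refitting
  # pls1_engine() on each fold (asserted against per-fold refits in the tests)
  G0 <- tcrossprod(x)
  g1 <- rowSums(G0)
  s11 <- sum(g1)
  tol <- 1e-12
  preds <- matrix(NA_real_, n, max_ncomp)
  for (i in seq_len(n)) {
    nf <- n - 1
    gi <- G0[-i, i]
    xm_dot <- (g1[-i] - gi) / nf          # X_{-i} %*% m
    mtm <- (s11 - 2 * g1[i] + G0[i, i]) / nf^2
    mtxi <- (g1[i] - G0[i, i]) / nf
    G <- G0[-i, -i] - outer(xm_dot, rep(1, nf)) -
      outer(rep(1, nf), xm_dot) + mtm
    kap <- gi - xm_dot - mtxi + mtm       # E0 %*% (x_i - m)
    ymean <- mean(y[-i])
    f <- y[-i] - ymean
    scale0 <- max(mean(abs(diag(G))), 1)
    cum <- numeric(max_ncomp)
    yhat <- ymean
    a_done <- 0L
    for (a in seq_len(max_ncomp)) {
      Gf <- G %*% f
      s2 <- sum(f * Gf)
      if (!is.finite(s2) || s2 <= tol * scale0 * max(sum(f^2), tol)) break
      t <- Gf[, 1] / sqrt(s2)
      tt <- sum(t^2)
      if (tt <= tol * scale0) break
      q <- sum(f * t) / tt
      tstar <- sum(kap * f) / sqrt(s2)
      yhat <- yhat + q * tstar
      cum[a] <- yhat
      a_done <- a
      Gt <- (G %*% t)[, 1]
      tGt <- sum(t * Gt)
      kap <- kap - tstar * Gt / tt - (sum(t * kap) / tt) * t +
        tstar * (tGt / tt^2) * t
      G <- G - (tcrossprod(Gt, t) + tcrossprod(t, Gt)) / tt +
        tcrossprod(t) * (tGt / tt^2)
      f <- f - q * t
    }
    if (a_done == 0L) {
      preds[i, ] <- ymean
    } else {
      # if rank truncated the fold, reuse the deepest available model
      preds[i, ] <- cum[pmin(seq_len(max_ncomp), a_done)]
    }
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  ncomp <- which.min(rmsecv) # which.min takes the first minimum: small count wins ties
  list(
    rmsecv = tibble::tibble(ncomp = seq_len(max_ncomp), rmsecv = rmsecv),
    ncomp = as.integer(ncomp),
    rmsecv_min = rmsecv[ncomp],
    r_cv = stats::cor(y, preds[, ncomp]),
    predictions = preds[, ncomp]
  )
}

#' Calibration metrics: Pearson correlation and RMSE
#'
#' @param y_true measured doses (mg/g), nonconstant for R.
#' @param y_pred predicted doses.
#' @return a tibble with columns `r` and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    rlang::abort("`y_true` and `y_pred` must have equal length >= 2.")
  }
  if (stats::var(y_true) == 0) {
    rlang::abort("`y_true` is constant; the correlation is undefined (RMSE via rmse()).")
  }
  tibble::tibble(r = stats::cor(y_true, y_pred), rmse = rmse(y_true, y_pred))
}

#' @rdname regression_metrics
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    rlang::abort("`y_true` and `y_pred` must have equal length.")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Principal component analysis of a spectra table
#'
#' Column-mean-centered PCA via the singular value decomposition
#' (`stats::prcomp`), with per-component explained variance
#' `100 * sigma_i^2 / sum(sigma^2)`. Used as the qualitative screen for
#' separating adulterated from pure samples before any calibration model.
#'
#' @param data a spectra tibble (or a bare matrix).
#' @param ncomp how many components to keep in the scores table.
#' @return an object of class `teaspec_pca`: `scores` (tibble with dose,
#'   set and PC columns), `explained_variance_pct` (all components),
#'   `loadings`.
#' @export
spectra_pca <- function(data, ncomp = 3) {
  if (is.data.frame(data)) {
    check_spectra(data)
    m <- spectra_matrix(data)
    meta <- data[c("dose", "set")]
  } else {
    m <- as.matrix(data)
    meta <- tibble::tibble(dose = rep(NA_real_, nrow(m)),
                           set = rep(NA_character_, nrow(m)))
  }
  if (nrow(m) < 2) rlang::abort("PCA needs at least 2 samples.")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(ncomp, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(ncomp), drop = FALSE])
  structure(list(
    scores = dplyr::bind_cols(meta, scores),
    explained_variance_pct = ev,
    loadings = pc$rotation,
    center = pc$center
  ), class = "teaspec_pca")
}

#' @export
print.teaspec_pca <- function(x, ...) {
  ev <- x$explained_variance_pct
  k <- min(3, length(ev))
  cat(sprintf("PCA: first %d components explain %s%% (cumulative %.1f%%)\n",
              k, paste(sprintf("%.1f", ev[seq_len(k)]), collapse = " + "),
              sum(ev[seq_len(k)])))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$x_mean) %||% as.character(seq_along(x$coefficients)),
    estimate = unname(x$coefficients)
  )
}

#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_variables = length(x$coefficients))
}

#' @export
tidy.teaspec_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$explained_variance_pct),
    explained_variance_pct = x$explained_variance_pct,
    cumulative_pct = cumsum(x$explained_variance_pct)
  )
}

#' Scatter plot of the first two principal components, coloured by dose
#'
#' @param object a `teaspec_pca`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.teaspec_pca <- function(object, ...) {
  ev <- object$explained_variance_pct
  ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, colour = .data$dose, shape = .data$set
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ev[1]),
      y = sprintf("PC2 (%.1f%%)", ev[2]),
      colour = "Dose (mg/g)", shape = NULL
    ) +
    ggplot2::theme_minimal()
}
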