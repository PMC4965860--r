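new_selection <- function(stage, indices, wavenumbers, trace, rmsecv) {
  structure(list(
    stage = stage,
    selected_indices = as.integer(indices),
    selected_wavenumbers = wavenumbers,
    rmsecv_trace = trace,
    rmsecv = rmsecv
  ), class = "teaspec_selection")
}

#' @export
print.teaspec_selection <- function(x, ...) {
  cat(sprintf("%s selection: %d wavenumber(s), RMSECV %.4g\n",
              x$stage, length(x$selected_indices), x$rmsecv))
  invisible(x)
}

#' @export
tidy.teaspec_selection <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    index = x$selected_indices,
    wavenumber = x$selected_wavenumbers
  )
}

#' @export
glance.teaspec_selection <- function(x, ...) {
  tibble::tibble(stage = x$stage,
                 n_selected = length(x$selected_indices),
                 rmsecv = x$rmsecv)
}

#' RMSECV trace of a selection stage
#'
#' @param object a `teaspec_selection`.
#' @param ... unused.
#' @return a ggplot object showing cross-validated error along the
#'   elimination/sampling path, with the retained step marked.
#' @export
autoplot.teaspec_selection <- function(object, ...) {
  tr <- object$rmsecv_trace
  xvar <- names(tr)[1]
  best <- tr[which.min(tr$rmsecv), ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data[[xvar]], y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = best, colour = "red", shape = 8, size = 3) +
    ggplot2::labs(title = sprintf("%s RMSECV trace", object$stage),
                  y = "RMSECV (mg/g)") +
    ggplot2::theme_minimal()
}

# contiguous interval assignment: near-equal widths, the remainder spread
# one extra point over the leading intervals
interval_blocks <- function(p, n_intervals) {
  base <- p %/% n_intervals
  rem <- p %% n_intervals
  widths <- base + (seq_len(n_intervals) <= rem)
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, seq)
}

#' Backward interval PLS (biPLS) wavenumber selection
#'
#' Splits the variables into `n_intervals` contiguous blocks of near-equal
#' width and eliminates intervals backward: at each round the interval
#' whose removal yields the lowest leave-one-out RMSECV PLS model on the
#' remainder is dropped. The full elimination path is walked down to a
#' single interval and the interval set with the global minimum RMSECV
#' along the path is returned (ties go to the earliest step).
#'
#' @param x predictor matrix (calibration samples by wavenumbers).
#' @param y dose vector.
#' @param grid wavenumber vector aligned with the columns of `x`.
#' @param n_intervals number of intervals (>= 2).
#' @param max_ncomp latent-variable cap for the inner PLS models.
#' @return a `teaspec_selection` (stage `"bipls"`) whose trace records the
#'   best RMSECV after each elimination round.
#' @export
select_bipls <- function(x, y, grid, n_intervals = 20, max_ncomp = 10) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (n_intervals < 2) rlang::abort("`n_intervals` must be >= 2.")
  if (n_intervals > p) rlang::abort("More intervals than variables.")
  blocks <- interval_blocks(p, n_intervals)
  score <- function(block_ids) {
    cols <- sort(unlist(blocks[block_ids]))
    cap <- min(max_ncomp, length(cols), nrow(x) - 2)
    pls_loo(x[, cols, drop = FALSE], y, cap)$rmsecv_min
  }
  alive <- seq_len(n_intervals)
  trace_rmsecv <- score(alive)
  trace_nvar <- p
  path <- list(alive)
  while (length(alive) > 1) {
    cand <- vapply(seq_along(alive),
                   function(j) score(alive[-j]), numeric(1))
    j <- which.min(cand)
    alive <- alive[-j]
    trace_rmsecv <- c(trace_rmsecv, cand[j])
    trace_nvar <- c(trace_nvar, sum(lengths(blocks[alive])))
    path <- c(path, list(alive))
  }

  best_step <- which.min(trace_rmsecv)
  keep <- sort(unlist(blocks[path[[best_step]]]))
  trace <- tibble::tibble(
    step = seq_along(trace_rmsecv) - 1L,
    n_intervals = n_intervals - (seq_along(trace_rmsecv) - 1L),
    n_vars = trace_nvar,
    rmsecv = trace_rmsecv
  )
  new_selection("bipls", keep, grid[keep], trace, trace_rmsecv[best_step])
}

#' Exponentially decreasing retention schedule of CARS
#'
#' The fraction of variables retained at Monte-Carlo run `i` is
#' `r_i = a * exp(-k * i)` with `a = exp(k)` and `k = log(p / 2) / (N - 1)`,
#' so that all `p` variables survive the first run (`r_1 = 1`) and exactly
#' two survive the last (`r_N = 2 / p`).
#'
#' @param i run index, `1 <= i <= N`.
#' @param n_runs total number of sampling runs `N` (>= 2).
#' @param p number of variables entering CARS (>= 2).
#' @return the retained fraction, strictly decreasing in `i`.
#' @export
edf_ratio <- function(i, n_runs, p) {
  if (p < 2) rlang::abort("`p` must be >= 2.")
  if (n_runs < 2) rlang::abort("`n_runs` must be >= 2.")
  if (any(i < 1 | i > n_runs)) rlang::abort("`i` must be in [1, n_runs].")
  k <- log(p / 2) / (n_runs - 1)
  exp(k) * exp(-k * i)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo survival-of-the-fittest selection. At run i a PLS model is
#' fit on a random `calibration_fraction` of the samples using the
#' currently eligible variables; variables are ranked by their normalized
#' absolute regression coefficients `w_j = |b_j| / sum(|b_j|)`; enforced
#' selection keeps the top `ceiling(p * r_i)` by weight (with `r_i` from
#' [edf_ratio()]); adaptive reweighted sampling then draws that many
#' variables with replacement with probability `w_j`, the distinct drawn
#' set becoming the eligible set. Each run is scored by the leave-one-out
#' RMSECV of a PLS model on its eligible set, and the minimum-RMSECV run
#' wins (ties to the earlier run). Deterministic given `seed`.
#'
#' @inheritParams select_bipls
#' @param n_runs number of sampling runs.
#' @param calibration_fraction fraction of samples drawn (without
#'   replacement) for the per-run coefficient fit.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return a `teaspec_selection` (stage `"cars"`) whose trace records
#'   per-run variable counts and RMSECV.
#' @export
select_cars <- function(x, y, grid, n_runs = 50, calibration_fraction = 0.8,
                        max_ncomp = 10, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) rlang::abort("CARS needs at least 2 variables.")
  if (calibration_fraction <= 0 || calibration_fraction > 1) {
    rlang::abort("`calibration_fraction` must be in (0, 1].")
  }
  set.seed(seed)
  eligible <- seq_len(p)
  runs <- integer(0); nvars <- integer(0); rmsecvs <- numeric(0)
  sets <- list()
  n_sub <- max(2L, floor(calibration_fraction * n))
  for (i in seq_len(n_runs)) {
    rows <- if (n_sub >= n) seq_len(n) else sort(sample.int(n, n_sub))
    xe <- x[rows, eligible, drop = FALSE]
    cap <- min(max_ncomp, length(eligible), length(rows) - 1)
    eng <- pls1_engine(xe, y[rows], cap, strict = FALSE)
    b <- abs(eng$coef_path[, eng$n_components])
    w <- if (sum(b) > 0) b / sum(b) else rep(1 / length(b), length(b))
    n_keep <- min(ceiling(p * edf_ratio(i, n_runs, p)), length(eligible))
    top <- order(w, decreasing = TRUE)[seq_len(n_keep)]
    eligible <- eligible[top]
    w <- w[top]
    # adaptive reweighted sampling: eligibility = distinct variables drawn
    drawn <- sample(seq_along(eligible), size = n_keep, replace = TRUE,
                    prob = if (sum(w) > 0) w else NULL)
    eligible <- sort(eligible[unique(drawn)])
    if (length(eligible) < 2) break
    cap_cv <- min(max_ncomp, length(eligible), n - 2)
    cv <- pls_loo(x[, eligible, drop = FALSE], y, cap_cv)
    runs <- c(runs, i)
    nvars <- c(nvars, length(eligible))
    rmsecvs <- c(rmsecvs, cv$rmsecv_min)
    sets[[length(sets) + 1L]] <- eligible
  }
  if (length(sets) == 0) {
    rlang::abort("CARS eliminated all variables before scoring any run.")
  }
  best <- which.min(rmsecvs)
  keep <- sets[[best]]
  trace <- tibble::tibble(run = runs, n_vars = nvars, rmsecv = rmsecvs)
  new_selection("cars", keep, grid[keep], trace, rmsecvs[best])
}

#' Successive projections algorithm (SPA)
#'
#' Builds, from every possible starting column, a chain that repeatedly
#' adds the candidate column with the largest norm of its component
#' orthogonal to the span of the columns already chosen (minimal
#' collinearity). Every chain prefix of length m in `[1, max_vars]` is
#' scored by the leave-one-out RMSECV of an ordinary multiple linear
#' regression on those m columns (closed-form PRESS), and the (start, m)
#' pair with minimum RMSECV wins; ties go to the smaller m, then the
#' smaller start index.
#'
#' @inheritParams select_bipls
#' @param max_vars longest chain considered; must be
#'   `<= min(rows - 1, cols)`.
#' @return a `teaspec_selection` (stage `"spa"`) whose trace records
#'   RMSECV by prefix length for the winning start.
#' @export
select_spa <- function(x, y, grid, max_vars = 25) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (max_vars < 1) rlang::abort("`max_vars` must be >= 1.")
  max_vars <- min(max_vars, n - 2, p)
  best <- list(rmsecv = Inf, m = Inf, start = Inf, chain = NULL,
               trace = NULL)
  for (s in seq_len(p)) {
    chain <- spa_chain(x, s, max_vars)
    cv <- vapply(seq_along(chain), function(m) {
      lm_loo_rmsecv(x[, chain[seq_len(m)], drop = FALSE], y)
    }, numeric(1))
    m <- which.min(cv)
    better <- cv[m] < best$rmsecv ||
      (cv[m] == best$rmsecv && (m < best$m || (m == best$m && s < best$start)))
    if (better) {
      best <- list(rmsecv = cv[m], m = m, start = s,
                   chain = chain[seq_len(m)],
                   trace = tibble::tibble(n_vars = seq_along(cv), rmsecv = cv))
    }
  }
  keep <- sort(best$chain)
  new_selection("spa", keep, grid[keep], best$trace, best$rmsecv)
}

# Gram-Schmidt chain with pivoting: starting at column `start`, repeatedly
# append the column with the largest residual norm orthogonal to the span
# of those already in the chain (ties -> smallest column index).
spa_chain <- function(x, start, max_vars) {
  p <- ncol(x)
  resid <- x
  chain <- integer(max_vars)
  chain[1] <- start
  for (step in seq_len(max_vars)) {
    if (step > 1) {
      norms <- sqrt(colSums(resid^2))
      norms[chain[seq_len(step - 1)]] <- -Inf
      chain[step] <- which.max(norms)
      if (!is.finite(norms[chain[step]]) || norms[chain[step]] < 1e-10) {
        return(chain[seq_len(step - 1)])
      }
    }
    v <- resid[, chain[step]]
    nv <- sum(v^2)
    if (nv < 1e-20) return(chain[seq_len(max(step - 1, 1))])
    resid <- resid - outer(v, colSums(resid * v) / nv)
  }
  chain
}

# closed-form leave-one-out RMSECV of ordinary least squares with intercept:
# PRESS residuals e_i / (1 - h_ii)
lm_loo_rmsecv <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  h <- stats::hat(cbind(1, x), intercept = FALSE)
  e <- fit$residuals / pmax(1 - h, 1e-12)
  sqrt(mean(e^2))
}

#' Run the hybrid biPLS -> CARS -> SPA selection cascade
#'
#' Each stage consumes only the variables surviving the previous stage;
#' indices in every returned `teaspec_selection` are reported in
#' original-grid coordinates, so the stage-wise selections are nested.
#' Any stage can be disabled; with all stages disabled a single
#' pass-through result with every variable is returned.
#'
#' @inheritParams select_bipls
#' @param stages character subset of `c("bipls", "cars", "spa")`, applied
#'   in that order.
#' @param n_intervals biPLS interval count.
#' @param cars_runs,calibration_fraction CARS settings (see
#'   [select_cars()]).
#' @param spa_max_vars SPA chain cap (see [select_spa()]).
#' @param seed seed for the CARS Monte-Carlo draws.
#' @return a named list of `teaspec_selection` objects, one per executed
#'   stage (plus a `"full"` pass-through when no stage is enabled).
#' @export
select_cascade <- function(x, y, grid,
                           stages = c("bipls", "cars", "spa"),
                           n_intervals = 20, max_ncomp = 10,
                           cars_runs = 50, calibration_fraction = 0.8,
                           spa_max_vars = 25, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(length(grid) == ncol(x))
  bad <- setdiff(stages, c("bipls", "cars", "spa"))
  if (length(bad)) rlang::abort(paste("Unknown stage(s):", paste(bad, collapse = ", ")))
  stages <- intersect(c("bipls", "cars", "spa"), stages)
  current <- seq_len(ncol(x))
  out <- list()
  if (length(stages) == 0) {
    out$full <- new_selection(
      "full", current, grid,
      tibble::tibble(step = 0L, n_vars = ncol(x), rmsecv = NA_real_),
      NA_real_
    )
    return(out)
  }
  for (stage in stages) {
    if (length(current) < 2) {
      rlang::abort(sprintf(
        "Stage `%s` received %d variable(s); cascade aborted after: %s.",
        stage, length(current), paste(names(out), collapse = ", ")
      ))
    }
    xs <- x[, current, drop = FALSE]
    gs <- grid[current]
    res <- switch(stage,
      bipls = select_bipls(xs, y, gs,
                           n_intervals = min(n_intervals, length(current)),
                           max_ncomp = max_ncomp),
      cars = select_cars(xs, y, gs, n_runs = cars_runs,
                         calibration_fraction = calibration_fraction,
                         max_ncomp = max_ncomp, seed = seed),
      spa = select_spa(xs, y, gs, max_vars = spa_max_vars)
    )
    # re-express in original-grid coordinates
    res$selected_indices <- current[res$selected_indices]
    res$selected_wavenumbers <- grid[res$selected_indices]
    current <- res$selected_indices
    out[[stage]] <- res
  }
  out
}
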