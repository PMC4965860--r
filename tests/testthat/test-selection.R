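test_that("the EDF retention schedule satisfies its boundary conditions exactly", {
  for (pn in list(c(2800, 50), c(100, 10), c(12, 5))) {
    p <- pn[1]; N <- pn[2]
    expect_equal(edf_ratio(1, N, p), 1)
    expect_equal(edf_ratio(N, N, p), 2 / p)
    r <- edf_ratio(seq_len(N), N, p)
    expect_true(all(diff(r) < 0))
  }
  expect_equal(edf_ratio(5, 10, 100), exp(-4 * log(50) / 9), tolerance = 1e-12)
  expect_equal(edf_ratio(50, 50, 2800), 7.1429e-4, tolerance = 1e-4)
  expect_error(edf_ratio(0, 10, 100), "in \\[1")
  expect_error(edf_ratio(1, 1, 100), ">= 2")
})

test_that("interval partition has near-equal widths with the remainder leading", {
  b <- teaspec:::interval_blocks(2800, 20)
  expect_length(b, 20)
  expect_true(all(lengths(b) == 140))
  b2 <- teaspec:::interval_blocks(11, 3)
  expect_equal(lengths(b2), c(4L, 4L, 3L))
  expect_equal(unlist(b2), 1:11)
})

test_that("biPLS retains the informative interval, agreeing with exhaustive search", {
  # 9 variables in 3 intervals; y depends only on interval 2 (cols 4:6)
  toy <- toy_linear(30, 9, informative = 4:6, seed = 21)
  sel <- select_bipls(toy$x, toy$y, grid = 1:9, n_intervals = 3,
                      max_ncomp = 3)
  expect_true(all(4:6 %in% sel$selected_indices))

  # exhaustive oracle over all non-empty interval subsets
  blocks <- teaspec:::interval_blocks(9, 3)
  subsets <- setdiff(seq_len(2^3 - 1), 0)
  scores <- vapply(subsets, function(mask) {
    ids <- which(bitwAnd(mask, 2^(0:2)) > 0)
    cols <- unlist(blocks[ids])
    pls_loo(toy$x[, cols, drop = FALSE], toy$y,
            min(3, length(cols)))$rmsecv_min
  }, numeric(1))
  best_ids <- which(bitwAnd(subsets[which.min(scores)], 2^(0:2)) > 0)
  expect_true(2 %in% best_ids)
  expect_true(all(unlist(blocks[best_ids]) %in% c(sel$selected_indices, 1:9)))

  expect_error(select_bipls(toy$x, toy$y, 1:9, n_intervals = 1), ">= 2")
})

test_that("one variable per interval reduces biPLS to greedy backward elimination", {
  toy <- toy_linear(15, 6, informative = c(2, 5), seed = 22, noise_sd = 0.4)
  sel <- select_bipls(toy$x, toy$y, grid = 1:6, n_intervals = 6,
                      max_ncomp = 3)

  # independent greedy oracle over single variables
  alive <- 1:6
  score <- function(cols) {
    pls_loo(toy$x[, cols, drop = FALSE], toy$y,
            min(3, length(cols)))$rmsecv_min
  }
  best_rmsecv <- score(alive); best_set <- alive
  while (length(alive) > 1) {
    cand <- vapply(seq_along(alive),
                   function(j) score(alive[-j]), numeric(1))
    j <- which.min(cand)
    alive <- alive[-j]
    if (cand[j] < best_rmsecv) {
      best_rmsecv <- cand[j]; best_set <- alive
    }
  }
  expect_equal(sel$selected_indices, sort(best_set))
  expect_equal(sel$rmsecv, best_rmsecv, tolerance = 1e-12)
})

test_that("CARS respects its boundary behaviour and is seed-reproducible", {
  # 2 variables, N = 2: r_N = 2/p retains everything
  toy2 <- toy_linear(12, 2, informative = 1:2, seed = 23, noise_sd = 0.1)
  sel2 <- select_cars(toy2$x, toy2$y, grid = 1:2, n_runs = 2,
                      calibration_fraction = 1, seed = 5)
  expect_setequal(sel2$selected_indices, 1:2)

  expect_equal(ceiling(2800 * edf_ratio(50, 50, 2800)), 2)

  toy <- toy_linear(25, 12, informative = c(3, 9), seed = 24, noise_sd = 0.2)
  a <- select_cars(toy$x, toy$y, 1:12, n_runs = 20, seed = 42)
  b <- select_cars(toy$x, toy$y, 1:12, n_runs = 20, seed = 42)
  expect_identical(a$selected_indices, b$selected_indices)
  expect_identical(a$rmsecv_trace, b$rmsecv_trace)
  c2 <- select_cars(toy$x, toy$y, 1:12, n_runs = 20, seed = 43)
  expect_false(identical(a$rmsecv_trace, c2$rmsecv_trace))
  expect_true(all(a$selected_indices %in% 1:12))
  expect_gt(nrow(a$rmsecv_trace), 0)
})

test_that("SPA projection chains match hand arithmetic and a pivoted orthogonalization oracle", {
  # columns c1 = [1,0], c2 = [0.5,0.5], c3 = [0,2]; from c1 the next pick
  # is c3 (orthogonal residual norm 2 vs 0.5)
  x <- cbind(c(1, 0), c(0.5, 0.5), c(0, 2))
  expect_equal(teaspec:::spa_chain(x, 1, 3)[1:2], c(1L, 3L))

  # orthogonal projection step: [1,1] against span{[1,0]} leaves [0,1]
  b <- c(1, 0); v <- c(1, 1)
  expect_equal(v - b * sum(v * b) / sum(b^2), c(0, 1))

  # pivoted Gram-Schmidt oracle on random 5 x 4 matrices
  gs_oracle <- function(x, start) {
    p <- ncol(x); chain <- start; basis <- x[, start, drop = FALSE]
    for (step in 2:p) {
      resid_norm <- vapply(seq_len(p), function(j) {
        if (j %in% chain) return(-Inf)
        r <- x[, j]
        for (k in seq_len(ncol(basis))) {
          bk <- basis[, k]
          r <- r - bk * sum(r * bk) / sum(bk^2)
        }
        sqrt(sum(r^2))
      }, numeric(1))
      nxt <- which.max(resid_norm)
      chain <- c(chain, nxt)
      r <- x[, nxt]
      for (k in seq_len(ncol(basis))) {
        bk <- basis[, k]
        r <- r - bk * sum(r * bk) / sum(bk^2)
      }
      basis <- cbind(basis, r)
    }
    chain
  }
  set.seed(26)
  for (rep in 1:5) {
    xr <- matrix(rnorm(20), 5, 4)
    for (s in 1:4) {
      expect_equal(teaspec:::spa_chain(xr, s, 4), as.integer(gs_oracle(xr, s)))
    }
  }
})

test_that("SPA selects a small informative subset by PRESS cross-validation", {
  toy <- toy_linear(30, 8, informative = c(2, 6), seed = 27, noise_sd = 0.05)
  sel <- select_spa(toy$x, toy$y, grid = 1:8, max_vars = 5)
  expect_true(all(c(2, 6) %in% sel$selected_indices))
  expect_lte(length(sel$selected_indices), 5)
  expect_error(select_spa(toy$x, toy$y, 1:8, max_vars = 0), ">= 1")
})

test_that("the cascade nests its stages and reports original-grid coordinates", {
  cfg <- small_config()
  sp <- preprocess_spectra(trim_spectra(simulate_spectra(cfg), 100, 100), "snv")
  cal <- sp[sp$set == "calibration", ]
  x <- spectra_matrix(cal); grid <- spectra_grid(cal)
  sel <- select_cascade(x, cal$dose, grid, n_intervals = 10,
                        cars_runs = 20, spa_max_vars = 10, max_ncomp = 5,
                        seed = 31)
  expect_named(sel, c("bipls", "cars", "spa"))
  expect_true(all(sel$cars$selected_indices %in% sel$bipls$selected_indices))
  expect_true(all(sel$spa$selected_indices %in% sel$cars$selected_indices))
  counts <- vapply(sel, function(s) length(s$selected_indices), integer(1))
  expect_true(all(diff(counts) <= 0))
  for (s in sel) {
    expect_false(anyDuplicated(s$selected_indices) > 0)
    expect_equal(s$selected_wavenumbers, grid[s$selected_indices])
  }
  # reproducible under the same seed
  sel2 <- select_cascade(x, cal$dose, grid, n_intervals = 10,
                         cars_runs = 20, spa_max_vars = 10, max_ncomp = 5,
                         seed = 31)
  expect_identical(lapply(sel, `[[`, "selected_indices"),
                   lapply(sel2, `[[`, "selected_indices"))

  none <- select_cascade(x, cal$dose, grid, stages = character(0))
  expect_named(none, "full")
  expect_equal(none$full$selected_indices, seq_along(grid))
})
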