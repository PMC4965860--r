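# reduced synthetic configuration: same structure as the default study
# design, coarser grid and fewer replicates, for fast end-to-end tests
small_config <- function(seed = 1L, noise = noise_model()) {
  synthetic_config(
    n_points = 1200,
    design = dose_design(
      levels = c(0.00, 0.15, 0.25, 0.35, 0.50, 0.65, 0.75, 0.85,
                 1.00, 1.10, 1.25, 1.40, 1.50),
      calibration_levels = c(0.00, 0.25, 0.50, 0.75, 1.00, 1.25, 1.50),
      replicates_per_level = ifelse(
        c(0.00, 0.15, 0.25, 0.35, 0.50, 0.65, 0.75, 0.85,
          1.00, 1.10, 1.25, 1.40, 1.50) %in%
          c(0.00, 0.25, 0.50, 0.75, 1.00, 1.25, 1.50), 6L, 4L)
    ),
    noise = noise,
    seed = seed
  )
}

quiet_noise <- function() {
  noise_model(additive_sd = 0, multiplicative_sd = 0,
              baseline_offset_sd = 0, baseline_slope_sd = 0)
}

talc_centers <- function() {
  vapply(talc_component()$peaks, `[[`, numeric(1), "center")
}

# noiseless toy with dose response confined to known columns
toy_linear <- function(n, p, informative, seed = 1, noise_sd = 0) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  y <- rowSums(x[, informative, drop = FALSE]) +
    stats::rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}
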