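test_that("mass_to_dose converts blended masses to mg/g and validates input", {
  expect_equal(mass_to_dose(6.00, 4.00), 1.50)
  expect_equal(mass_to_dose(0.00, 4.00), 0.00)
  expect_equal(mass_to_dose(2.00, 4.00), 0.50)
  expect_error(mass_to_dose(1, 0), "positive")
  expect_error(mass_to_dose(-1, 4), "nonnegative")
})

test_that("peak evaluation honours apex, half-maximum and additivity", {
  grid <- seq(900, 1100, by = 0.5)
  for (shape in c("gaussian", "lorentzian")) {
    comp <- component_spectrum("x", list(peak_spec(1016, 1, 20, shape)))
    a <- eval_component(comp, grid)
    expect_equal(a[grid == 1016], 1.0)
    expect_equal(a[grid == 1016 - 10], 0.5, tolerance = 1e-12)
    expect_equal(a[grid == 1016 + 10], 0.5, tolerance = 1e-12)
  }
  p1 <- peak_spec(980, 0.7, 30)
  p2 <- peak_spec(1040, 1.2, 15, "lorentzian")
  both <- eval_component(component_spectrum("x", list(p1, p2)), grid)
  each <- eval_component(component_spectrum("x", list(p1)), grid) +
    eval_component(component_spectrum("x", list(p2)), grid)
  expect_equal(both, each)
  expect_warning(
    eval_component(component_spectrum("x", list(peak_spec(2000, 1, 20))), grid),
    "outside the grid span"
  )
})

test_that("default pure-component spectra are nonnegative on the raw grid", {
  grid <- seq(400, 4000, length.out = 3700)
  expect_true(all(eval_component(tea_component(), grid) >= 0))
  expect_true(all(eval_component(talc_component(), grid) >= 0))
})

test_that("simulation is deterministic and linear in dose when noiseless", {
  cfg <- small_config(noise = quiet_noise())
  sp <- simulate_spectra(cfg)
  expect_identical(sp, simulate_spectra(cfg))

  grid <- spectra_grid(sp)
  a_tea <- eval_component(cfg$tea, grid)
  m <- spectra_matrix(sp)
  zero <- m[sp$dose == 0, , drop = FALSE]
  expect_equal(unname(zero[1, ]), a_tea, tolerance = 1e-12)
  expect_true(all(apply(zero, 1, function(r) all(r == zero[1, ]))))

  d1 <- m[which(sp$dose == 1.00)[1], ] - a_tea
  d05 <- m[which(sp$dose == 0.50)[1], ] - a_tea
  expect_equal(unname(d1), unname(2 * d05), tolerance = 1e-10)
  expect_true(all(m >= 0))
})

test_that("the default design reproduces the 13-level study layout", {
  cfg <- synthetic_config()
  sp <- simulate_spectra(cfg)
  expect_setequal(unique(sp$dose),
                  c(0.00, 0.15, 0.25, 0.35, 0.50, 0.65, 0.75, 0.85,
                    1.00, 1.10, 1.25, 1.40, 1.50))
  expect_equal(sum(sp$set == "calibration"), 140)
  expect_equal(nrow(sp), sum(cfg$design$replicates_per_level))
  expect_length(spectra_grid(sp), 3700)
})

test_that("noise substreams are independent: disabling one source leaves the others' draws unchanged", {
  base <- small_config()
  no_add <- small_config(noise = noise_model(
    additive_sd = 0,
    multiplicative_sd = base$noise$multiplicative_sd,
    baseline_offset_sd = base$noise$baseline_offset_sd,
    baseline_slope_sd = base$noise$baseline_slope_sd
  ))
  only_add <- small_config(noise = noise_model(
    additive_sd = base$noise$additive_sd, multiplicative_sd = 0,
    baseline_offset_sd = 0, baseline_slope_sd = 0
  ))
  quiet <- small_config(noise = quiet_noise())
  eps_a <- spectra_matrix(simulate_spectra(base)) -
    spectra_matrix(simulate_spectra(no_add))
  eps_b <- spectra_matrix(simulate_spectra(only_add)) -
    spectra_matrix(simulate_spectra(quiet))
  expect_equal(eps_a, eps_b, tolerance = 1e-12)
})

test_that("level-wise split partitions samples by dose and ignores row order", {
  cfg <- small_config()
  sp <- simulate_spectra(cfg)
  parts <- split_by_level(sp, cfg$design)
  expect_equal(nrow(parts$calibration) + nrow(parts$prediction), nrow(sp))
  expect_true(all(parts$prediction$dose %in% cfg$design$prediction_levels))
  expect_true(all(parts$calibration$dose %in% cfg$design$calibration_levels))
  expect_true(all(parts$prediction$dose != 0.65 |
                    parts$prediction$set == "prediction"))

  shuffled <- sp[sample(nrow(sp)), ]
  parts2 <- split_by_level(shuffled, cfg$design)
  expect_setequal(
    do.call(paste, parts$calibration[1:2]),
    do.call(paste, parts2$calibration[1:2])
  )

  all_cal <- dose_design(cfg$design$levels,
                         calibration_levels = cfg$design$levels,
                         replicates_per_level = 1L)
  parts3 <- split_by_level(sp, all_cal)
  expect_equal(nrow(parts3$prediction), 0)
  expect_equal(nrow(parts3$calibration), nrow(sp))

  bad <- sp
  bad$dose[1] <- 99
  expect_error(split_by_level(bad, cfg$design), "99")
})

test_that("spectra round-trip through the CSV matrix format", {
  cfg <- small_config()
  sp <- simulate_spectra(cfg)[1:5, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, path)
  back <- read_spectra(path)
  expect_equal(spectra_grid(back), spectra_grid(sp), tolerance = 1e-9)
  expect_equal(spectra_matrix(back), spectra_matrix(sp), tolerance = 1e-12)
  expect_equal(back$dose, sp$dose)
  expect_equal(back$set, sp$set)
})

test_that("YAML configuration files override generator defaults", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "grid: {start: 500, stop: 3500, n_points: 600}",
    "kappa: 0.1",
    "seed: 7",
    "noise: {additive_sd: 0.001}",
    "design:",
    "  levels: [0.0, 0.5, 1.0]",
    "  calibration_levels: [0.0, 1.0]",
    "  replicates_per_level: 3"
  ), path)
  cfg <- read_synthetic_config(path)
  expect_equal(cfg$n_points, 600L)
  expect_equal(cfg$kappa, 0.1)
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$noise$additive_sd, 0.001)
  expect_equal(cfg$noise$multiplicative_sd, noise_model()$multiplicative_sd)
  expect_equal(cfg$design$prediction_levels, 0.5)
  sp <- simulate_spectra(cfg)
  expect_equal(nrow(sp), 9)
})
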