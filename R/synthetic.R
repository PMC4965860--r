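#' Convert an adulterant mass to a dose
#'
#' Doses are expressed as mg of adulterant per g of matrix, the unit used
#' throughout the calibration models.
#'
#' @param adulterant_mass mass of adulterant, mg. Must be >= 0.
#' @param matrix_mass mass of the matrix it is blended into, g. Must be > 0.
#' @return dose in mg/g.
#' @examples
#' mass_to_dose(6.00, 4.00) # 1.5 mg/g
#' @export
mass_to_dose <- function(adulterant_mass, matrix_mass) {
  if (any(matrix_mass <= 0)) {
    rlang::abort("`matrix_mass` must be positive (g).")
  }
  if (any(adulterant_mass < 0)) {
    rlang::abort("`adulterant_mass` must be nonnegative (mg).")
  }
  adulterant_mass / matrix_mass
}

#' Peak and component definitions for the spectra generator
#'
#' `peak_spec()` describes one absorbance band; `component_spectrum()`
#' bundles the bands of one pure material (tea or talc) together with a
#' slowly varying nonnegative broad background (a very wide Gaussian),
#' so that the evaluated pure spectrum is nonnegative everywhere.
#'
#' @param center band center, cm^-1.
#' @param height apex absorbance, AU (>= 0).
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @export
peak_spec <- function(center, height, fwhm, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (height < 0) rlang::abort("`height` must be >= 0.")
  if (fwhm <= 0) rlang::abort("`fwhm` must be > 0.")
  structure(list(center = center, height = height, fwhm = fwhm, shape = shape),
            class = "peak_spec")
}

#' @rdname peak_spec
#' @param name component label, e.g. `"tea"` or `"talc"`.
#' @param peaks list of [peak_spec()] objects.
#' @param background_amplitude amplitude of the broad background, AU.
#' @param background_center center of the broad background, cm^-1.
#' @param background_scale length-scale of the broad background, cm^-1.
#' @export
component_spectrum <- function(name, peaks,
                               background_amplitude = 0,
                               background_center = 2000,
                               background_scale = 1500) {
  if (background_amplitude < 0 || background_scale <= 0) {
    rlang::abort("Background amplitude must be >= 0 and scale > 0.")
  }
  structure(list(
    name = name, peaks = peaks,
    background_amplitude = background_amplitude,
    background_center = background_center,
    background_scale = background_scale
  ), class = "component_spectrum")
}

eval_peak <- function(peak, grid) {
  u <- (grid - peak$center) / peak$fwhm
  switch(peak$shape,
    gaussian = peak$height * exp(-4 * log(2) * u^2),
    lorentzian = peak$height / (1 + 4 * u^2)
  )
}

#' Evaluate a pure-component spectrum on a wavenumber grid
#'
#' Pointwise sum of the component's peak shapes plus its broad background.
#' A peak whose center lies outside the grid span raises a warning but is
#' still evaluated, since its tails may fall in range.
#'
#' @param component a [component_spectrum()].
#' @param grid strictly increasing wavenumber vector, cm^-1.
#' @return absorbance vector (AU), nonnegative.
#' @export
eval_component <- function(component, grid) {
  if (is.unsorted(grid, strictly = TRUE)) {
    rlang::abort("`grid` must be strictly increasing.")
  }
  centers <- vapply(component$peaks, `[[`, numeric(1), "center")
  out_of_span <- centers < grid[1] | centers > grid[length(grid)]
  if (any(out_of_span)) {
    rlang::warn(paste0(
      "Peak center(s) outside the grid span: ",
      paste(centers[out_of_span], collapse = ", ")
    ))
  }
  a <- rep(0, length(grid))
  for (p in component$peaks) a <- a + eval_peak(p, grid)
  if (component$background_amplitude > 0) {
    a <- a + component$background_amplitude *
      exp(-0.5 * ((grid - component$background_center) /
                    component$background_scale)^2)
  }
  a
}

#' Default pure-component band libraries
#'
#' Band centers follow the published assignments for green-tea powder
#' (broad organic bands near 1050, 1401, 1617, 2920 and 3117 cm^-1 on a
#' smooth background) and talc (sharp Si-O-Si bands at 995/1016/1050 cm^-1
#' with the 1016 cm^-1 band dominant, plus 1182, 1249, 1340, 1444, 1631 and
#' 2296 cm^-1). Heights and widths are generator defaults in AU and cm^-1.
#'
#' @return a [component_spectrum()].
#' @export
tea_component <- function() {
  component_spectrum(
    "tea",
    peaks = list(
      peak_spec(1050, 0.30, 160),
      peak_spec(1401, 0.45, 110),
      peak_spec(1617, 0.50, 110),
      peak_spec(2920, 0.35, 140),
      peak_spec(3117, 0.55, 500)
    ),
    background_amplitude = 0.15,
    background_center = 1800,
    background_scale = 1500
  )
}

#' @rdname tea_component
#' @export
talc_component <- function() {
  component_spectrum(
    "talc",
    peaks = list(
      peak_spec(995, 0.55, 12),
      peak_spec(1016, 1.00, 14),
      peak_spec(1050, 0.50, 14),
      peak_spec(1182, 0.30, 16),
      peak_spec(1249, 0.30, 16),
      peak_spec(1340, 0.25, 14),
      peak_spec(1444, 0.35, 18),
      peak_spec(1631, 0.30, 18),
      peak_spec(2296, 0.20, 20)
    )
  )
}

#' Dose design: levels, replicates and the level-wise set split
#'
#' The default mirrors the adulteration study design: 13 dose levels from
#' 0.00 to 1.50 mg/g, of which 7 (0.00, 0.25, 0.50, 0.75, 1.00, 1.25,
#' 1.50 mg/g) form the calibration set and the remaining 6 the prediction
#' set. The study's 210 samples over these levels imply no integer
#' per-level count, so the generator defaults to 20 replicates per
#' calibration level (140 calibration samples, as published) and 12 per
#' prediction level.
#'
#' @param levels dose levels, mg/g (all >= 0).
#' @param calibration_levels subset of `levels` forming the calibration set;
#'   the complement forms the prediction set.
#' @param replicates_per_level positive integer vector, one per level
#'   (recycled if length 1).
#' @export
dose_design <- function(levels,
                        calibration_levels,
                        replicates_per_level) {
  if (any(levels < 0)) rlang::abort("Doses must be >= 0 (mg/g).")
  if (anyDuplicated(levels)) rlang::abort("`levels` must be distinct.")
  if (!all(calibration_levels %in% levels)) {
    rlang::abort("`calibration_levels` must be a subset of `levels`.")
  }
  replicates_per_level <- rep_len(as.integer(replicates_per_level),
                                  length(levels))
  if (any(replicates_per_level < 1)) {
    rlang::abort("`replicates_per_level` must be positive.")
  }
  structure(list(
    levels = levels,
    replicates_per_level = replicates_per_level,
    calibration_levels = calibration_levels,
    prediction_levels = setdiff(levels, calibration_levels)
  ), class = "dose_design")
}

#' @rdname dose_design
#' @export
default_dose_design <- function() {
  lv <- c(0.00, 0.15, 0.25, 0.35, 0.50, 0.65, 0.75, 0.85,
          1.00, 1.10, 1.25, 1.40, 1.50)
  cal <- c(0.00, 0.25, 0.50, 0.75, 1.00, 1.25, 1.50)
  reps <- ifelse(lv %in% cal, 20L, 12L)
  dose_design(lv, cal, reps)
}

#' Per-spectrum artefact model
#'
#' The generator distorts each noiseless spectrum with a multiplicative
#' gain (scatter analogue), an affine baseline (offset + slope in
#' wavenumber) and i.i.d. additive noise, so that scatter-correcting
#' preprocessing such as SNV has something to correct. Setting all
#' standard deviations to 0 recovers the noiseless model exactly.
#'
#' @param additive_sd sd of i.i.d. additive noise, AU.
#' @param multiplicative_sd sd of the per-spectrum gain around 1
#'   (dimensionless).
#' @param baseline_offset_sd sd of the per-spectrum baseline offset, AU.
#' @param baseline_slope_sd sd of the per-spectrum baseline slope,
#'   AU per cm^-1.
#' @export
noise_model <- function(additive_sd = 0.015,
                        multiplicative_sd = 0.05,
                        baseline_offset_sd = 0.01,
                        baseline_slope_sd = 5e-6) {
  sds <- c(additive_sd, multiplicative_sd, baseline_offset_sd,
           baseline_slope_sd)
  if (any(sds < 0)) rlang::abort("All noise sds must be >= 0.")
  structure(list(
    additive_sd = additive_sd,
    multiplicative_sd = multiplicative_sd,
    baseline_offset_sd = baseline_offset_sd,
    baseline_slope_sd = baseline_slope_sd
  ), class = "noise_model")
}

#' Synthetic-study configuration
#'
#' The default raw grid is 3700 evenly spaced points on 400--4000 cm^-1,
#' chosen so that deleting the first 500 and last 400 points (see
#' [trim_spectra()]) leaves exactly 2800 variables on roughly
#' 887--3612 cm^-1. `kappa` scales the talc component per unit dose; its
#' default makes the talc contribution at the top dose (1.5 mg/g) about
#' 10% of the tea apex, i.e. an adulteration signal invisible to the eye.
#'
#' @param grid_start,grid_stop,n_points raw wavenumber grid, cm^-1.
#' @param tea,talc [component_spectrum()] objects.
#' @param kappa talc response coefficient, AU per (mg/g); must be > 0.
#' @param design a [dose_design()].
#' @param noise a [noise_model()].
#' @param seed integer master seed; it is expanded into independent
#'   substreams for gain, baseline and additive noise, so switching one
#'   noise source off does not perturb the draws of the others.
#' @export
synthetic_config <- function(grid_start = 400, grid_stop = 4000,
                             n_points = 3700,
                             tea = tea_component(),
                             talc = talc_component(),
                             kappa = 0.05,
                             design = default_dose_design(),
                             noise = noise_model(),
                             seed = 1L) {
  if (kappa <= 0) rlang::abort("`kappa` must be > 0.")
  if (n_points < 2) rlang::abort("`n_points` must be >= 2.")
  structure(list(
    grid_start = grid_start, grid_stop = grid_stop,
    n_points = as.integer(n_points),
    tea = tea, talc = talc, kappa = kappa,
    design = design, noise = noise, seed = as.integer(seed)
  ), class = "synthetic_config")
}

config_grid <- function(config) {
  seq(config$grid_start, config$grid_stop, length.out = config$n_points)
}

# Deterministic substream seeds below 2^31, derived from one master seed.
substream_seed <- function(seed, id) {
  as.integer((abs(as.numeric(seed)) * 48271 + id * 69621) %% 2147483629 + 1)
}

#' Simulate a raw (untrimmed) spectra table
#'
#' For sample s with dose c_s the spectrum is
#' `gain_s * (A_tea + c_s * kappa * A_talc) + baseline_s + eps_s`,
#' a Beer--Lambert linear dose response distorted by the artefact model of
#' [noise_model()]. Deterministic given `config$seed`; the sample count is
#' the sum of the design's replicates. The `set` column is assigned
#' level-wise from the design.
#'
#' @param config a [synthetic_config()].
#' @return a spectra tibble (see [as_spectra()]).
#' @export
simulate_spectra <- function(config) {
  design <- config$design
  if (length(design$levels) == 0) rlang::abort("Empty dose design.")
  grid <- config_grid(config)
  a_tea <- eval_component(config$tea, grid)
  a_talc <- eval_component(config$talc, grid)
  dose <- rep(design$levels, design$replicates_per_level)
  n <- length(dose)
  p <- length(grid)

  nm <- config$noise
  # each artefact source draws under its own substream seed, so disabling
  # one source leaves the draws of the others untouched
  draw <- function(id, how_many, sd) {
    if (sd == 0) return(rep(0, how_many))
    set.seed(substream_seed(config$seed, id))
    stats::rnorm(how_many, 0, sd)
  }
  gain <- 1 + draw(1L, n, nm$multiplicative_sd)
  offset <- draw(2L, n, nm$baseline_offset_sd)
  slope <- draw(3L, n, nm$baseline_slope_sd)
  eps <- matrix(draw(4L, n * p, nm$additive_sd), n, p)

  pure <- outer(rep(1, n), a_tea) + (dose * config$kappa) %o% a_talc
  wc <- grid - mean(grid)
  a <- gain * pure + outer(offset, rep(1, p)) + slope %o% wc + eps
  as_spectra(grid, a, dose,
             set = ifelse(dose %in% design$calibration_levels,
                          "calibration", "prediction"))
}

#' Read a synthetic-study configuration from a YAML file
#'
#' Recognised keys mirror [synthetic_config()]: `grid` (`start`, `stop`,
#' `n_points`), `kappa`, `seed`, `noise` (the four sds), `design`
#' (`levels`, `calibration_levels`, `replicates_per_level`), and optional
#' `tea` / `talc` blocks with a `peaks` list of `{center, height, fwhm,
#' shape}` entries plus background fields. Missing keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- synthetic_config()
  if (!is.null(y$grid)) {
    cfg$grid_start <- y$grid$start %||% cfg$grid_start
    cfg$grid_stop <- y$grid$stop %||% cfg$grid_stop
    cfg$n_points <- as.integer(y$grid$n_points %||% cfg$n_points)
  }
  cfg$kappa <- y$kappa %||% cfg$kappa
  cfg$seed <- as.integer(y$seed %||% cfg$seed)
  if (!is.null(y$noise)) {
    cfg$noise <- noise_model(
      additive_sd = y$noise$additive_sd %||% cfg$noise$additive_sd,
      multiplicative_sd = y$noise$multiplicative_sd %||% cfg$noise$multiplicative_sd,
      baseline_offset_sd = y$noise$baseline_offset_sd %||% cfg$noise$baseline_offset_sd,
      baseline_slope_sd = y$noise$baseline_slope_sd %||% cfg$noise$baseline_slope_sd
    )
  }
  if (!is.null(y$design)) {
    lv <- y$design$levels %||% cfg$design$levels
    cfg$design <- dose_design(
      levels = lv,
      calibration_levels = y$design$calibration_levels %||%
        intersect(cfg$design$calibration_levels, lv),
      replicates_per_level = y$design$replicates_per_level %||% 12L
    )
  }
  parse_component <- function(block, default) {
    if (is.null(block)) return(default)
    peaks <- lapply(block$peaks, function(p) {
      peak_spec(p$center, p$height, p$fwhm, p$shape %||% "gaussian")
    })
    component_spectrum(
      block$name %||% default$name, peaks,
      background_amplitude = block$background_amplitude %||% 0,
      background_center = block$background_center %||% 2000,
      background_scale = block$background_scale %||% 1500
    )
  }
  cfg$tea <- parse_component(y$tea, cfg$tea)
  cfg$talc <- parse_component(y$talc, cfg$talc)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
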