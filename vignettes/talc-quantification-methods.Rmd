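---
title: "Methods: quantifying talc adulteration in tea from FT-IR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying talc adulteration in tea from FT-IR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Talcum powder (Mg₃[Si₄O₁₀](OH)₂) is an occasional adulterant of ground
tea. Its sharp Si–O–Si absorbance near 990–1055 cm⁻¹ sits on top of the
broad organic bands of tea, so FT-IR transmission spectra of KBr-pelleted
tea powder carry a quantifiable dose signal even when the spectra look
identical to the eye. `teaspec` implements the full calibration workflow:
synthetic spectra generation, preprocessing, qualitative PCA screening, a
hybrid wavenumber-selection cascade (biPLS → CARS → SPA), and linear (PLS)
plus nonlinear (ELM) dose models.

## The synthetic-spectra generator

No public spectra exist for this problem, so the package ships a
generator that reproduces the statistical structure the analysis assumes.
Sample $s$ with dose $c_s$ (mg talc per g tea) on wavenumber grid $w$ is

$$A_s(w) = g_s\,\bigl(A_\text{tea}(w) + c_s\,\kappa\,A_\text{talc}(w)\bigr)
          + a_s + b_s\,(w - \bar w) + \varepsilon_s(w),$$

a Beer–Lambert linear dose response distorted by a per-spectrum gain
$g_s \sim 1 + N(0, \sigma_g)$ (the scatter analogue), an affine baseline
(offset $a_s$, slope $b_s$) and i.i.d. additive noise $\varepsilon$.
Each pure component is a sum of Gaussian/Lorentzian bands: talc at 995,
1016 (dominant), 1050, 1182, 1249, 1340, 1444, 1631 and 2296 cm⁻¹; tea as
broad bands at 1050, 1401, 1617, 2920 and 3117 cm⁻¹ on a smooth
background. The O–H stretch band at 3117 cm⁻¹ is given a 500 cm⁻¹ FWHM so
that, as in real tea spectra, absorbance stays well away from zero across
3000–3600 cm⁻¹; narrow toy bands would leave the spectral edges empty,
which real pellets do not show.

Defaults that define the study conditions:

* **Grid**: 3700 evenly spaced points on 400–4000 cm⁻¹. Deleting the
  first 500 and last 400 points (the published edge-noise deletion) then
  leaves exactly 2800 variables on ≈887–3612 cm⁻¹. We prioritise the
  variable count of 2800 over the printed endpoints (881–3581 cm⁻¹),
  because every percentage in the analysis is quoted against 2800.
* **Dose design**: the 13 printed levels 0.00–1.50 mg/g; the 7 levels
  0.00, 0.25, 0.50, 0.75, 1.00, 1.25, 1.50 mg/g form the calibration set.
  210 samples over 13 levels admit no uniform integer replicate count, so
  the defaults are 20 replicates per calibration level (140 calibration
  samples, the published count) and 12 per prediction level (72). The
  printed pairing of 0.50 mg with the 0.15 mg/g level conflicts with
  0.50/4.00 = 0.125; the generator exposes the printed level list
  verbatim and does not resolve the arithmetic.
* **Response** $\kappa = 0.05$ AU/(mg/g): the talc contribution at the
  top dose is ≈10 % of the tea apex — an adulteration signal invisible to
  the naked eye, which is the study's premise.
* **Noise**: gain sd 0.05, baseline offset sd 0.01 AU, baseline slope sd
  5×10⁻⁶ AU/cm⁻¹, additive sd 0.015 AU. The additive level is calibrated
  so that the default conditions reproduce the error magnitudes the
  original study reports for its full-spectrum SNV PLS model
  (R_P ≈ 0.95–0.98, RMSEP ≈ 0.11–0.13 mg/g). A much cleaner generator
  would make every wavenumber equally predictive and the RMSECV
  landscape flat, which is not the regime the method was designed for.
* **Randomness**: one integer seed, expanded into independent substreams
  for gain, baseline and additive noise, so switching one source off
  does not perturb the draws of the others.

What the generator does **not** emulate: tea-to-tea compositional
variability (every sample shares one tea spectrum), instrument line
shape, detector nonlinearity, water-vapour/CO₂ bands, and curved
baselines. Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not calibration transfer to real
instruments.

## Preprocessing

Three row-wise treatments are compared against raw spectra, mirroring
the study's Table of preprocessing models:

* **Smoothing** — centered moving average, window 9 points, shrinking
  symmetrically at the edges. The source study never defines its
  "smoothing"; a moving average is the simplest defensible reading and
  the window is exposed.
* **Normalize** — division by the spectrum maximum (apex = 1), a common
  IR convention; unit-length normalization is provided as
  `normalize_length()` for comparison.
* **SNV** — $(x - \bar x)/s_x$ with the sample (n−1) standard deviation.
  SNV removes any per-spectrum affine distortion exactly,
  `snv(a + b·x) = snv(x)`, which is precisely the gain/offset model the
  generator injects.

Trimming is positional (500 + 400 points), matching the published
"spectral data were deleted" wording, and is applied before
preprocessing (the deletion happened at acquisition time in the study).

## Calibration models and metrics

PLS is single-response NIPALS with mean-centered (not variance-scaled)
predictors; for one response the inner loop is non-iterative, and all
nested component counts come from one deflation pass. The
latent-variable count for every reported model is chosen by
leave-one-out cross-validation (the study's "full cross validation"),
minimising RMSECV with ties to the smaller count; the cap defaults to
15 for calibration models and 10 inside selection. LOO is computed in
the kernel (Gram-matrix) form, algebraically identical to refitting on
each fold but independent of the variable count, which keeps the
interval-elimination search affordable; tests assert equality with
explicit per-fold refits to 10⁻⁸.

Models are summarised by the six-metric sextet R_C/RMSEC (calibration),
R_CV/RMSECV (cross-validation) and R_P/RMSEP (prediction), with R the
Pearson correlation of measured and predicted dose. PCA (centered SVD)
provides the qualitative screen; per-component contributions are
$100\,\sigma_i^2/\sum\sigma^2$.

## The selection cascade

* **biPLS** splits the 2800 variables into 20 equal-width intervals
  (140 points each; remainders, when present, go one extra point to the
  leading intervals) and eliminates backward: at each round the interval
  whose removal gives the lowest LOO-RMSECV model is dropped. The study
  states only that "the model with lowest RMSECV was chosen", so the
  implementation walks the full elimination path and keeps the
  global-minimum interval set along it.
* **CARS** runs N = 50 Monte-Carlo sampling runs at calibration fraction
  0.8 (common CARS practice; the study states neither). Run $i$ keeps
  the top $\lceil p\,r_i\rceil$ variables by normalized absolute PLS
  coefficient (enforced selection) with the exponentially decreasing
  schedule $r_i = a e^{-k i}$, $a = e^k$, $k = \ln(p/2)/(N-1)$, so
  $r_1 = 1$ and $r_N = 2/p$; adaptive reweighted sampling then draws
  that many variables with replacement, the distinct set surviving. The
  minimum-RMSECV run wins, ties to the earlier run.
* **SPA** builds, from every start column, the chain that repeatedly
  adds the column with the largest residual orthogonal to the span of
  those chosen, and scores every prefix by closed-form PRESS LOO of an
  ordinary multiple regression (SPA subsets are built to be
  well-conditioned, so MLR rather than PLS is the conventional scorer).
  Ties go to the shorter prefix, then the smaller start.

Each stage consumes only the survivors of the previous one and reports
indices in original-grid coordinates, so selections are nested. The
cascade operates on the **SNV-preprocessed calibration spectra**. The
original study runs its cascade on the SNV model's spectra; we follow
it rather than routing on the winner of the preprocessing comparison,
because under the calibrated noise level the comparison can be won by
smoothing, which would hand the cascade scatter-uncorrected spectra.
An explicit `selection_method` override (including `"best"`) remains.

### Composition of the selected set

On the default conditions the final SPA set concentrates on the talc
apexes (the 1016 cm⁻¹ cluster, 1050, 1182) but also retains
reference wavenumbers in flat spectral regions. This is a real property
of multivariate selection on scatter-corrected spectra, not an artefact:
after SNV the row standard deviation depends (weakly) on dose, so flat
extreme-absorbance columns carry an indirect dose signal and serve as
correction channels; CARS and SPA legitimately keep some. The original
study shows the same composition — of its 18 selected wavenumbers it
assigns only 6 to talc bands. Users who need chemically pure selections
should interpret the per-stage RMSECV traces together with the
univariate dose-correlation profile, which the generator shows to be
cleanly concentrated at the talc apexes.

## ELM

The nonlinear model is a single-hidden-layer extreme learning machine:
inputs min-max scaled to [−1, 1] per feature (raw absorbance would
saturate the activation), hidden weights and biases drawn once from
Uniform[−1, 1] under the model seed, sigmoid activation, and output
weights by minimum-norm least squares (SVD pseudo-inverse, no ridge
term). The hidden-node count — the only manual parameter — is swept
over 1–80 as in the study, scored by LOO RMSECV on calibration data
with the hidden layer redrawn per fit; prediction samples are
structurally unreachable from the sweep. Whether the study chose its 36
nodes on cross-validation or on the prediction set is unstated; the
sweep here never touches prediction data.

## Numerical choices and degenerate inputs

* Ties everywhere resolve to the smallest index / earliest step /
  fewest components, making all deterministic paths reproducible.
* Rank-deficient folds inside LOO truncate to the deepest achievable
  component count; a strict fit (`fit_pls()`) errors instead, with a
  suggestion to request fewer components.
* Constant responses yield a zero coefficient vector and mean
  predictions; constant spectra raise an error in SNV (zero spread) and
  max-normalization (zero maximum); zero-range ELM features pass
  through at 0 with a warning.
* Selected wavenumbers are displayed rounded to integer cm⁻¹ but kept
  at full precision internally.

## Problem sizes used by the test-suite

The unit and property tests run the full workflow on a reduced
configuration (1200-point grid, 6/4 replicates per level, ≈66 samples)
chosen to exercise every code path at interactive speed; the
parameter-recovery check runs the complete default study (2800
variables after trimming, 212 samples) once. The end-to-end determinism
property is size-independent and is asserted on the reduced
configuration.

## Known limitations

* Single-response PLS only; no kernel or multi-block variants.
* The generator's artefact model is affine per spectrum; curved
  baselines and multiplicative effects that vary across the band are
  out of scope.
* CARS inherits the usual Monte-Carlo variability: with very clean
  data, many runs tie within noise and the minimum-RMSECV rule can
  retain large sets.
* The published metric values of the original study depend on
  undeposited spectra and are not reproduction targets; the package
  reproduces the method, the study design and the published arithmetic.
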