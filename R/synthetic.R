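## Seeded generators for every experiment design the pipeline consumes.
##
## The generators are the study conditions in code: 12 samples at a 30 min
## period, loads of order 5-100 nmol in the standard 12-well transwell
## geometry, multiplicative log-normal measurement noise on collected
## amounts (spectrophotometric error scales with signal; default cv 0.03).
## Noise-free output is the exact forward model, so the generators double
## as oracles for the inversion round-trip tests.

#' Measurement-noise model
#'
#' @param kind `"none"` or `"multiplicative-lognormal"`.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (dimensionless, `>= 0`).
#' @param seed Integer seed; identical seeds reproduce identical sequences.
#' @return An object of class `noise_model`.
#' @export
noiseModel <- function(kind = c("none", "multiplicative-lognormal"),
                       cv = 0.03, seed = 1L) {
  kind <- match.arg(kind)
  check_numeric(cv, "cv", non_negative = TRUE, scalar = TRUE)
  check_numeric(seed, "seed", scalar = TRUE)
  structure(list(kind = kind, cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

# mean-preserving multiplicative log-normal noise, isolated RNG state
apply_noise <- function(x, noise) {
  if (noise$kind == "none" || noise$cv == 0) return(x)
  sdlog <- sqrt(log(1 + noise$cv^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
}

#' Experiment design record
#'
#' @param design One of `"dilution"`, `"rinse"`, `"basolateral_load"`,
#'   `"apical_load"`, `"barrier_culture"`. A rinse/dilution design loads
#'   the well once and replaces with compound-free medium thereafter.
#' @param load_nmol Initial load (nmol).
#' @param n_samples Number of sampling intervals (`>= 3`).
#' @param tau Sampling period (min).
#' @param geometry A [transwellGeometry()].
#' @return An object of class `experiment_design`.
#' @export
experimentDesign <- function(design = c("rinse", "dilution",
                                        "basolateral_load", "apical_load",
                                        "barrier_culture"),
                             load_nmol = 18, n_samples = 12, tau = 30,
                             geometry = transwellGeometry()) {
  design <- match.arg(design)
  check_numeric(load_nmol, "load_nmol", non_negative = TRUE, scalar = TRUE)
  check_numeric(n_samples, "n_samples", positive = TRUE, scalar = TRUE)
  if (n_samples < 3) stop_invalid("n_samples must be at least 3")
  check_numeric(tau, "tau", positive = TRUE, scalar = TRUE)
  geometry$tau <- tau
  structure(list(design = design, load_nmol = load_nmol,
                 n_samples = as.integer(n_samples), tau = tau,
                 geometry = geometry), class = "experiment_design")
}

#' Generate a single-compartment rinse/dilution sample sequence
#'
#' Forward-simulates the single-compartment sampling model for a
#' single-load design and applies measurement noise.
#'
#' @param params A [samplingParams()].
#' @param design An [experimentDesign()] of kind `"rinse"` or
#'   `"dilution"`.
#' @param noise A [noiseModel()].
#' @return Numeric vector of sampled amounts (nmol) with attribute
#'   `truth` (the noise-free trajectory).
#' @export
genSingleCompartment <- function(params, design,
                                 noise = noiseModel("none")) {
  if (!design$design %in% c("rinse", "dilution"))
    stop_invalid("design must be 'rinse' or 'dilution', got '",
                 design$design, "'")
  inputs <- c(design$load_nmol, numeric(design$n_samples - 1L))
  tr <- forwardSimulate(params, inputs)
  structure(apply_noise(tr$S, noise), truth = tr)
}

# default per-interval transfer fraction for the synthetic apical-load
# design: the fraction implied by the bare-membrane permeability
# (slope ~5.66 uL/min over Va = 500 uL, 30 min: 1 - exp(-0.34) ~ 0.3)
DEFAULT_TRANSFER_FRACTION <- 0.3

#' Generate a two-compartment calibration sample sequence
#'
#' For a `"basolateral_load"` design the load is split between the basal
#' and lateral sub-volumes by `params$r`. For an `"apical_load"` design a
#' per-interval transmembrane series is required; by default a geometric
#' transfer series `I_b_i = A1 * f * (1 - f)^(i-1)` with `f = 0.3` (the
#' transfer fraction implied by the measured bare-membrane permeability)
#' whose infinite sum is exactly the apical load.
#'
#' @param params A [subParams()].
#' @param design An [experimentDesign()] of kind `"basolateral_load"` or
#'   `"apical_load"`.
#' @param noise A [noiseModel()].
#' @param transmembrane Optional numeric vector of per-interval
#'   transmembrane amounts (nmol) for the apical design.
#' @param transfer_fraction Per-interval transfer fraction of the default
#'   geometric series.
#' @return Numeric vector of sampled amounts (nmol) with attributes
#'   `truth` (the `sub_trajectory`) and `I_b` (the transmembrane series).
#' @export
genTwoCompartment <- function(params, design, noise = noiseModel("none"),
                              transmembrane = NULL,
                              transfer_fraction = DEFAULT_TRANSFER_FRACTION) {
  n <- design$n_samples
  if (design$design == "basolateral_load") {
    load <- splitInitialLoad(design$load_nmol, params$r)
    Ib <- c(load[["I1_b"]], numeric(n - 1L))
    Il <- c(load[["I1_l"]], numeric(n - 1L))
  } else if (design$design == "apical_load") {
    if (is.null(transmembrane)) {
      f <- transfer_fraction
      transmembrane <- design$load_nmol * f * (1 - f)^(seq_len(n) - 1L)
    }
    if (length(transmembrane) != n)
      stop_invalid("transmembrane series must have length n_samples")
    Ib <- transmembrane
    Il <- numeric(n)
  } else {
    stop_invalid("design must be 'basolateral_load' or 'apical_load', got '",
                 design$design, "'")
  }
  tr <- forwardSimulateSub(params, Ib, Il)
  structure(apply_noise(tr$S_l, noise), truth = tr, I_b = Ib)
}

#' Generate a full barrier-culture experiment
#'
#' Runs the barrier PDE to obtain per-interval transmembrane amounts `J`,
#' feeds them as basal inputs into the sub-compartment sampler, and
#' returns both the observable sample sequence and the ground-truth flux
#' series for recovery tests.
#'
#' @param bparams A [barrierParams()].
#' @param sparams A [subParams()].
#' @param design An [experimentDesign()] of kind `"barrier_culture"`;
#'   `load_nmol` sets the initial apical amount (`ca0 = load / Va`).
#' @param noise A [noiseModel()].
#' @param n_nodes,dt_factor Discretization, as in [simulateBarrier()].
#' @return A list with `samples` (noisy sampled amounts, nmol), `flux`
#'   (ground-truth `flux_series`), and `run` (the `barrier_run`).
#' @export
genBarrierExperiment <- function(bparams, sparams, design,
                                 noise = noiseModel("none"),
                                 n_nodes = 50, dt_factor = 0.4) {
  if (design$design != "barrier_culture")
    stop_invalid("design must be 'barrier_culture', got '",
                 design$design, "'")
  geom <- design$geometry
  sched <- samplingSchedule(design$n_samples, design$tau)
  ca0 <- design$load_nmol / geom$Va * 1000   # nmol over uL -> uM
  run <- simulateBarrier(bparams, geom, sched, ca0, n_nodes, dt_factor)
  tr <- forwardSimulateSub(sparams, run$J, numeric(design$n_samples))
  A <- design$load_nmol - cumsum(run$J)
  flux <- fluxSeries(I_b = run$J, A = A, T_b = tr$T_b,
                     delta_c = deltaC(A, tr$T_b, geom), tau = design$tau)
  list(samples = apply_noise(tr$S_l, noise), flux = flux, run = run)
}

#' Generate synthetic absorbance spectra for a concentration series
#'
#' Emits one spectrum per concentration: a Gaussian peak at the
#' calibration wavelength (width 30 nm, truncated 100 nm out so the
#' long-wavelength baseline window stays signal-free) whose peak absorbance
#' inverts the calibration map, superposed on a linear baseline, with optional
#' multiplicative noise on the absorbance. Concentrations outside the
#' calibration range `[0.013, 10]` uM are flagged.
#'
#' @param conc_series Concentrations (uM).
#' @param cal A [calibrationModel()].
#' @param baseline_slope Baseline slope in absorbance per nm.
#' @param baseline_offset Baseline intercept in absorbance units.
#' @param noise A [noiseModel()].
#' @param wavelengths Wavelength grid (nm).
#' @return A list of [spectrum()] objects; each carries attribute
#'   `in_range`.
#' @export
genSpectra <- function(conc_series, cal, baseline_slope = 0,
                       baseline_offset = 0, noise = noiseModel("none"),
                       wavelengths = seq(370, 750, by = 2)) {
  check_numeric(conc_series, "conc_series", non_negative = TRUE)
  lapply(seq_along(conc_series), function(i) {
    conc <- conc_series[i]
    peakA <- absorbanceFromConcentration(conc, cal)
    shape <- peakA * exp(-(wavelengths - cal$wavelength)^2 / (2 * 30^2))
    # truncate the peak so the 550-750 nm baseline window stays signal-free
    shape[abs(wavelengths - cal$wavelength) >= 100] <- 0
    base <- baseline_offset + baseline_slope * wavelengths
    noise_i <- noise
    if (noise$kind != "none") {
      noise_i$seed <- noise$seed + i
      shape <- apply_noise(pmax(shape, 1e-12), noise_i)
    }
    sp <- spectrum(wavelengths, shape + base)
    attr(sp, "in_range") <- conc >= 0.013 && conc <= 10
    sp
  })
}
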