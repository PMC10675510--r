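## Readers and writers for the pipeline's plain-text interchange formats.
##
## CSV dialect: comma separator, "." decimal, UTF-8, Unix newlines, header
## required. All numeric columns carry lab units in their names (nmol, uL,
## min, uM, mm/h). Parameter records and run configuration are YAML with
## unit-suffixed keys.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid("malformed CSV ", path, ": missing column(s) ",
                 paste(missing, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_invalid("malformed CSV ", path, ": non-numeric value in column '",
                   col, "' at data row ", bad)
    }
  }
  df
}

write_csv_unix <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read / write a sample-sequence CSV
#'
#' Columns `sample_index,time_min,amount_nmol`.
#'
#' @param path File path.
#' @return `readSamples()`: a data frame with the three columns.
#' @export
readSamples <- function(path) {
  read_csv_checked(path, c("sample_index", "time_min", "amount_nmol"))
}

#' @rdname readSamples
#' @param amounts Sampled amounts (nmol).
#' @param tau Sampling period (min).
#' @export
writeSamples <- function(amounts, path, tau = 30) {
  n <- length(amounts)
  write_csv_unix(data.frame(sample_index = seq_len(n),
                            time_min = seq_len(n) * tau,
                            amount_nmol = as.numeric(amounts)), path)
}

#' Read / write a flux-series CSV
#'
#' Columns `sample_index,I_b_nmol,A_nmol,delta_c_uM` (plus `T_b_nmol`,
#' kept so the series round-trips losslessly).
#'
#' @param path File path.
#' @param tau Sampling period (min) to attach on read.
#' @return `readFluxSeries()`: a [fluxSeries()].
#' @export
readFluxSeries <- function(path, tau = 30) {
  df <- read_csv_checked(path, c("sample_index", "I_b_nmol", "A_nmol",
                                 "delta_c_uM", "T_b_nmol"))
  fluxSeries(I_b = df$I_b_nmol, A = df$A_nmol, T_b = df$T_b_nmol,
             delta_c = df$delta_c_uM, tau = tau)
}

#' @rdname readFluxSeries
#' @param flux A [fluxSeries()].
#' @export
writeFluxSeries <- function(flux, path) {
  write_csv_unix(data.frame(sample_index = seq_along(flux$I_b),
                            I_b_nmol = flux$I_b, A_nmol = flux$A,
                            delta_c_uM = flux$delta_c,
                            T_b_nmol = flux$T_b), path)
}

#' Read / write a spectrum CSV
#'
#' Columns `wavelength_nm,absorbance`, one row per grid point.
#'
#' @param path File path.
#' @return `readSpectrum()`: a [spectrum()].
#' @export
readSpectrum <- function(path) {
  df <- read_csv_checked(path, c("wavelength_nm", "absorbance"))
  spectrum(df$wavelength_nm, df$absorbance)
}

#' @rdname readSpectrum
#' @param spec A [spectrum()].
#' @export
writeSpectrum <- function(spec, path) {
  write_csv_unix(data.frame(wavelength_nm = spec$wavelengths,
                            absorbance = spec$absorbance), path)
}

#' Read / write a barrier-run CSV
#'
#' Columns `time_min,J_nmol,ca_uM,N_nmol`.
#'
#' @param path File path.
#' @param run A `barrier_run` (see [simulateBarrier()]).
#' @export
writeBarrierRun <- function(run, path) {
  write_csv_unix(data.frame(time_min = run$times, J_nmol = run$J,
                            ca_uM = run$ca_series, N_nmol = run$N_series),
                 path)
}

#' @rdname writeBarrierRun
#' @export
readBarrierRun <- function(path) {
  read_csv_checked(path, c("time_min", "J_nmol", "ca_uM", "N_nmol"))
}

## ---- parameter records (YAML, unit-suffixed keys) ----

#' Write / read model parameters as structured-text (YAML) records
#'
#' Each parameter class maps to a flat YAML record with unit-suffixed
#' keys, e.g. `P0_mm_per_h`. Fit metadata (`objective`) is carried along
#' when present.
#'
#' @param x A `sampling_params`, `sub_params`, `barrier_params`,
#'   `calibration_model` or `geometry` object.
#' @param path File path.
#' @export
writeParams <- function(x, path) {
  rec <- if (inherits(x, "sampling_params")) {
    list(type = "sampling_params", kon = x$kon, koff = x$koff, q = x$q)
  } else if (inherits(x, "sub_params")) {
    list(type = "sub_params", kon_b = x$kon_b, koff_b = x$koff_b,
         q_b = x$q_b, kon_l = x$kon_l, koff_l = x$koff_l, q_l = x$q_l,
         r = x$r)
  } else if (inherits(x, "barrier_params")) {
    list(type = "barrier_params", D_um2_per_min = x$D, Kcell = x$Kcell,
         P0_mm_per_h = x$P0, M_nmol_per_h_cm2 = x$M, H_um = x$H)
  } else if (inherits(x, "calibration_model")) {
    list(type = "calibration_model", wavelength_nm = x$wavelength,
         linear_coeff_uM = x$linear_coeff, power_coeff_uM = x$power_coeff,
         exponent = x$exponent)
  } else if (inherits(x, "geometry")) {
    list(type = "geometry", Va_uL = x$Va, Vb_uL = x$Vb,
         V_basolateral_uL = x$V_basolateral, area_cm2 = x$area,
         tau_min = x$tau)
  } else stop_invalid("unsupported parameter object of class ",
                      paste(class(x), collapse = "/"))
  if (!is.null(attr(x, "objective")))
    rec$objective <- as.numeric(attr(x, "objective"))
  yaml::write_yaml(rec, path, precision = 15)
  invisible(path)
}

#' @rdname writeParams
#' @export
readParams <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  rec <- yaml::read_yaml(path)
  switch(rec$type,
    sampling_params = samplingParams(rec$kon, rec$koff, rec$q),
    sub_params = subParams(rec$kon_b, rec$koff_b, rec$q_b,
                           rec$kon_l, rec$koff_l, rec$q_l, rec$r),
    barrier_params = barrierParams(rec$D_um2_per_min, rec$Kcell,
                                   rec$P0_mm_per_h, rec$M_nmol_per_h_cm2,
                                   rec$H_um),
    calibration_model = calibrationModel(rec$wavelength_nm,
                                         rec$linear_coeff_uM,
                                         rec$power_coeff_uM, rec$exponent),
    geometry = transwellGeometry(rec$Va_uL, rec$Vb_uL,
                                 rec$V_basolateral_uL, rec$area_cm2,
                                 rec$tau_min),
    stop_invalid("unknown parameter record type: ", rec$type))
}

## ---- run configuration ----

config_known_keys <- c("Va_uL", "Vb_uL", "V_basolateral_uL", "area_cm2",
                       "tau_min", "seed", "calibration", "out_dir",
                       "verbosity")

#' Read a run-configuration YAML file
#'
#' Known keys: geometry (`Va_uL`, `Vb_uL`, `V_basolateral_uL`, `area_cm2`,
#' `tau_min`), `seed`, `calibration` (`"DMEM"` or `"HPMI"` or a parameter
#' record path), `out_dir`, `verbosity`. Unknown keys are errors, which
#' catches typos.
#'
#' @param path File path.
#' @return A list with a [transwellGeometry()] under `$geometry` plus the
#'   remaining entries.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  geom <- transwellGeometry(
    Va = cfg$Va_uL %||% 500, Vb = cfg$Vb_uL %||% 110,
    V_basolateral = cfg$V_basolateral_uL %||% 1800,
    area = cfg$area_cm2 %||% 0.6, tau = cfg$tau_min %||% 30)
  c(list(geometry = geom),
    cfg[setdiff(names(cfg), c("Va_uL", "Vb_uL", "V_basolateral_uL",
                              "area_cm2", "tau_min"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
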