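## Diffusion-partition-metabolism model of the cell layer.
##
## The intracellular concentration profile c(h, t) obeys a 1D diffusion
## equation on [0, H]. At the apical surface the profile is pinned to
## Kcell * ca (fast partition equilibrium with the apical medium); at the
## basal surface the intra-layer diffusive flux equals the flux through the
## porous transwell membrane, P0 * A * (cB/Kcell - cb). The apical
## compartment drains through the layer and through a constant areal
## metabolic rate M; the basal compartment fills until each sampling event
## empties it. All interface units are lab units (mm/h, nmol/h cm^2, uM,
## uL, min); conversions happen at the boundary of the C++ stepper.

#' Barrier-layer parameters
#'
#' @param D Diffusivity of the compound within the cell layer (um^2/min).
#' @param Kcell Partition (membrane-binding affinity) coefficient,
#'   dimensionless ratio of adsorption to desorption rate constants; only
#'   the ratio enters the model.
#' @param P0 Diffusive permeability of the bare transwell membrane (mm/h).
#' @param M Areal metabolic elimination rate (nmol/h cm^2), `>= 0`.
#' @param H Cell-layer thickness (um).
#' @return An object of class `barrier_params`.
#' @examples
#' barrierParamsStudy()  # VERO E6 layer fit: D 1.8, Kcell 250, P0 5.33, M 0.81
#' @export
barrierParams <- function(D, Kcell, P0, M, H = 10) {
  for (nm in c("D", "Kcell", "P0", "H"))
    check_numeric(get(nm), nm, positive = TRUE, scalar = TRUE)
  check_numeric(M, "M", non_negative = TRUE, scalar = TRUE)
  structure(list(D = D, Kcell = Kcell, P0 = P0, M = M, H = H),
            class = "barrier_params")
}

#' @rdname barrierParams
#' @export
barrierParamsStudy <- function() barrierParams(1.8, 250, 5.33, 0.81, 10)

#' @export
print.barrier_params <- function(x, ...) {
  cat(sprintf(
    "<barrier_params> D = %.3g um^2/min, Kcell = %.4g, P0 = %.3g mm/h, M = %.3g nmol/h cm^2, H = %g um\n",
    x$D, x$Kcell, x$P0, x$M, x$H))
  cat(sprintf("  closed-form overall permeability P = %.3g mm/h\n",
              closedFormP(x)))
  invisible(x)
}

#' Periodic sampling schedule
#'
#' @param n_samples Number of sampling events.
#' @param tau Sampling period (min).
#' @param times Alternatively, explicit strictly increasing sampling times
#'   (min), first one `> 0`.
#' @return Numeric vector of sampling times with class
#'   `sampling_schedule`.
#' @export
samplingSchedule <- function(n_samples = 12, tau = 30, times = NULL) {
  if (is.null(times)) {
    check_numeric(n_samples, "n_samples", positive = TRUE, scalar = TRUE)
    check_numeric(tau, "tau", positive = TRUE, scalar = TRUE)
    times <- seq_len(n_samples) * tau
  }
  check_numeric(times, "times", positive = TRUE)
  if (any(diff(times) <= 0))
    stop_invalid("sampling times must be strictly increasing")
  structure(as.numeric(times), class = "sampling_schedule")
}

mm_h_to_um_min <- function(x) x * 1000 / 60
um_min_to_mm_h <- function(x) x * 60 / 1000

#' Simulate a barrier-culture sampling experiment
#'
#' Integrates the coupled PDE/ODE system by explicit finite differences
#' from `cb = cB = c(h) = 0`, `ca = ca0`. At each sampling time the basal
#' content `J_i = cb * Vb` is collected and `cb` reset to zero. The time
#' step is `dt_factor * dh^2 / D` (default safety factor 0.4, below the 0.5
#' explicit-Euler stability bound); larger factors are refused.
#'
#' @param params A [barrierParams()].
#' @param geom A [transwellGeometry()].
#' @param schedule A [samplingSchedule()] (or numeric sampling times, min).
#' @param ca0 Initial apical concentration (uM).
#' @param n_nodes Spatial grid nodes over `[0, H]` (default 50).
#' @param dt_factor Time-step safety factor, must be `< 0.5`.
#' @param hold_reservoirs If `TRUE`, `ca` and `cb` are held fixed (infinite
#'   reservoirs, no sampling resets) and `J` reports the instantaneous
#'   membrane flux in nmol/min at the scheduled times; used for
#'   steady-state checks.
#' @param cb_fixed Basal concentration in reservoir mode (uM).
#' @return An object of class `barrier_run`: list with `J` (collected
#'   amounts, nmol), `ca_series` (uM), `N_series` (nmol in the layer),
#'   `cb_series`, final `profile` (uM, intracellular frame) on `h_grid`
#'   (um), `metabolized` and `collected` totals (nmol), `times` (min).
#' @export
simulateBarrier <- function(params, geom = transwellGeometry(),
                            schedule = samplingSchedule(), ca0 = 10,
                            n_nodes = 50, dt_factor = 0.4,
                            hold_reservoirs = FALSE, cb_fixed = 0) {
  check_numeric(ca0, "ca0", non_negative = TRUE, scalar = TRUE)
  if (dt_factor >= 0.5 || dt_factor <= 0)
    stop_invalid("dt_factor must lie in (0, 0.5): explicit Euler is ",
                 "unstable at or above 0.5")
  if (n_nodes < 5) stop_invalid("n_nodes must be at least 5")
  times <- as.numeric(schedule)
  res <- .barrier_euler_cpp(params$D, params$Kcell,
                            mm_h_to_um_min(params$P0), params$M / 60,
                            params$H, as.integer(n_nodes), dt_factor,
                            ca0, geom$Va, geom$Vb, geom$area,
                            times, hold_reservoirs, cb_fixed)
  structure(c(res, list(times = times,
                        h_grid = seq(0, params$H, length.out = n_nodes),
                        params = params, geom = geom, ca0 = ca0)),
            class = "barrier_run")
}

#' @export
print.barrier_run <- function(x, ...) {
  cat(sprintf(
    "<barrier_run> %d sampling events to t = %g min; collected %.4g nmol, metabolized %.4g nmol, apical ca = %.4g uM\n",
    length(x$J), max(x$times), x$collected, x$metabolized,
    x$ca_series[length(x$ca_series)]))
  invisible(x)
}

#' Closed-form overall permeability of layer plus membrane
#'
#' In series, the cell layer (conductance `D * Kcell / H`) and the porous
#' membrane (conductance `P0`) combine into
#' `P = P0 * D * Kcell / (H * P0 + D * Kcell)`.
#'
#' @param params A [barrierParams()].
#' @return Overall diffusive permeability in mm/h.
#' @examples
#' closedFormP(barrierParamsStudy())  # ~1.8 mm/h, i.e. ~2 mm/h
#' @export
closedFormP <- function(params) {
  P0 <- mm_h_to_um_min(params$P0)           # um/min
  DK <- params$D * params$Kcell             # um^2/min
  um_min_to_mm_h(P0 * DK / (params$H * P0 + DK))
}

#' Single-window apparent permeability
#'
#' The standard estimator `P = Q / (A * T * delta_c)`: amount collected over
#' a window divided by area, duration and driving concentration difference.
#' With Q in nmol, A in cm^2, T in h and delta_c in uM (= 1 nmol/cm^3 per
#' uM), the quotient is in cm/h and is returned in mm/h.
#'
#' @param Q Amount collected during the window (nmol).
#' @param area Barrier area (cm^2).
#' @param T_h Window duration (h).
#' @param dc Concentration difference across the barrier (uM), non-zero.
#' @return Apparent permeability in mm/h.
#' @export
apparentPermeability <- function(Q, area, T_h, dc) {
  check_numeric(Q, "Q", non_negative = TRUE, scalar = TRUE)
  check_numeric(area, "area", positive = TRUE, scalar = TRUE)
  check_numeric(T_h, "T_h", positive = TRUE, scalar = TRUE)
  check_numeric(dc, "dc", scalar = TRUE)
  if (dc == 0) stop_invalid("delta_c must be non-zero")
  10 * Q / (area * T_h * dc)   # cm/h -> mm/h; 1 uM = 1 nmol/cm^3
}

#' Amount of compound within the layer
#'
#' Trapezoidal quadrature of the (intracellular-frame) concentration
#' profile times the area: `N = A * integral c(h) dh`. Exact for linear
#' profiles.
#'
#' @param profile Concentration profile (uM) on a uniform grid over
#'   `[0, H]`.
#' @param H Layer thickness (um).
#' @param area Layer area (cm^2).
#' @return Amount in nmol.
#' @export
totalInLayer <- function(profile, H, area) {
  check_numeric(profile, "profile", non_negative = TRUE)
  n <- length(profile)
  dh <- H / (n - 1)
  1e-4 * area * sum((profile[-1] + profile[-n]) / 2 * dh)
}

#' Fit the barrier model to an estimated flux sequence
#'
#' Minimizes the log-scale loss between the model-predicted collected
#' amounts `J_i` and the observed per-interval transmembrane amounts.
#' `D`, `Kcell`, `P0` and `M` are fitted in log-space (all positive); `H`
#' is held fixed, since thickness and diffusivity act nearly
#' interchangeably and thickness is available from histology.
#'
#' An asymptotic budget penalty (`penalty_weight *
#' (asymptoticPenalty(J, A1) / A1)^2`, demanding that the extrapolated
#' total collected amount reach the initial apical load) can be added for
#' data where metabolic loss is believed negligible. It is off by default:
#' whenever `M > 0` part of the load is eliminated before it can ever be
#' collected, so the extrapolated total falls short of the load *at the
#' true parameters* and the penalty biases the fit. See the methods
#' vignette.
#'
#' @param flux_obs A `flux_series` or numeric vector of per-interval
#'   transmembrane amounts (nmol).
#' @param H_fixed Fixed layer thickness (um).
#' @param geom A [transwellGeometry()].
#' @param schedule A [samplingSchedule()] matching the observations.
#' @param ca0 Initial apical concentration (uM).
#' @param init Starting [barrierParams()]; default
#'   `(D = 1, Kcell = 100, P0 = 5, M = 0.1)`.
#' @param n_nodes,dt_factor Discretization, as in [simulateBarrier()].
#' @param floor Log-loss floor (nmol).
#' @param penalty_weight Weight of the asymptotic budget penalty
#'   (default 0; see Details).
#' @return Fitted [barrierParams()] with attributes `objective` and
#'   `counts`.
#' @export
fitBarrier <- function(flux_obs, H_fixed = 10, geom = transwellGeometry(),
                       schedule = samplingSchedule(), ca0 = 10,
                       init = barrierParams(1, 100, 5, 0.1, H_fixed),
                       n_nodes = 50, dt_factor = 0.4, floor = 1e-9,
                       penalty_weight = 0) {
  I_obs <- if (inherits(flux_obs, "flux_series")) flux_obs$I_b else flux_obs
  check_numeric(I_obs, "flux_obs")
  if (any(I_obs <= 0))
    stop_invalid("flux sequence must be strictly positive for the ",
                 "log-scale loss; floor the observations first")
  A1 <- ca0 * geom$Va / 1000
  # generous physical bounds on the search region (log scale); outside
  # them the objective grows quadratically without simulating, which keeps
  # line searches from requesting integrations with astronomically many
  # stability-limited steps (dt ~ 1/D)
  z_lo <- log(c(1e-4, 1e-2, 1e-3, 1e-6))
  z_hi <- log(c(50, 1e6, 1e3, 1e3))
  obj <- function(z) {
    excess <- sum(pmax(z - z_hi, 0)^2 + pmax(z_lo - z, 0)^2)
    if (excess > 0) return(1e4 * (1 + excess))
    p <- exp(z)
    run <- simulateBarrier(barrierParams(p[1], p[2], p[3],
                                         max(p[4], 1e-12), H_fixed),
                           geom, schedule, ca0, n_nodes, dt_factor)
    J <- pmax(run$J, floor)
    pen <- if (penalty_weight > 0) {
      tryCatch(as.numeric(asymptoticPenalty(run$J, A1)) / A1,
               error = function(e) 1)
    } else 0
    sum((log(J) - log(I_obs))^2) + penalty_weight * pen^2
  }
  z0 <- log(c(init$D, init$Kcell, init$P0, init$M))
  fit <- stats::optim(z0, obj, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (fit2$value < fit$value) fit <- fit2
  if (!is.finite(fit$value))
    stop_diagnostic("barrier fit did not converge",
                    data = list(par = exp(fit$par), value = fit$value))
  p <- exp(fit$par)
  out <- barrierParams(p[1], p[2], p[3], p[4], H_fixed)
  attr(out, "objective") <- fit$value
  attr(out, "counts") <- fit$counts
  out
}
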