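# Sub-compartment model: recurrence, two-stage fit, flux reconstruction,
# permeability regression.

test_that("pass-through and reduction limits hold", {
  # all six parameters zero: samples are just the summed inputs
  p0 <- subParams(0, 0, 0, 0, 0, 0)
  Ib <- c(1, 2, 0.5); Il <- c(3, 0, 0.25)
  expect_equal(forwardSimulateSub(p0, Ib, Il)$S_l, Ib + Il,
               tolerance = 1e-14)
  # lateral stage transparent: reduces to the single-compartment model
  p <- subParams(0.1, 0.2, 0.5, 0, 0, 0)
  I <- c(100, 0, 0)
  expect_equal(forwardSimulateSub(p, I, c(0, 0, 0))$S_l,
               forwardSimulate(samplingParams(0.1, 0.2, 0.5), I)$S,
               tolerance = 1e-12)
})

test_that("mass is conserved across both sub-volumes", {
  set.seed(21)
  for (rep in 1:25) {
    p <- random_sub_params()
    Ib <- runif(8, 0, 10); Il <- runif(8, 0, 10)
    tr <- forwardSimulateSub(p, Ib, Il)
    err <- abs(sum(Ib + Il) -
               (sum(tr$S_l) + tr$x_b[8] + tr$y_b[8] + tr$x_l[8] + tr$y_l[8])) /
      sum(Ib + Il)
    expect_lt(err, 1e-12)
  }
})

test_that("initial load splits exactly by the basal volume fraction", {
  expect_equal(splitInitialLoad(18, 0.1),
               c(I1_b = 1.8, I1_l = 16.2), tolerance = 1e-14)
  expect_equal(sum(splitInitialLoad(7.3, 110 / 1800)), 7.3,
               tolerance = 1e-14)
  expect_equal(unname(splitInitialLoad(18, 1e-9)[1]), 1.8e-8,
               tolerance = 1e-12)
  expect_error(splitInitialLoad(18, 1.2), class = "transflux_invalid_input")
})

test_that("flux estimation inverts the forward model exactly", {
  set.seed(22)
  sp <- subParamsStudy()
  for (rep in 1:5) {
    Ib <- c(runif(1, 2, 8), runif(11, 0.05, 2))
    tr <- forwardSimulateSub(sp, Ib, numeric(12))
    fl <- estimateFluxes(tr$S_l, sp, A1 = sum(Ib))
    expect_lt(max(abs(fl$I_b - Ib) / Ib), 1e-9)
    # apical bookkeeping: amounts decrease by the cumulative flux
    expect_equal(fl$A, sum(Ib) - cumsum(Ib), tolerance = 1e-9)
  }
})

test_that("optimization-based flux estimation agrees with inversion", {
  sp <- subParamsStudy()
  SA <- genTwoCompartment(sp, experimentDesign("apical_load", 18, 12))
  exact <- estimateFluxes(SA, sp, 18)
  opt <- estimateFluxes(SA, sp, 18, method = "optimize")
  expect_lt(max(abs(opt$I_b - exact$I_b) / exact$I_b), 1e-6)
})

test_that("concentration differences follow the two-volume formula", {
  geom <- transwellGeometry()
  # second term vanishes: 5 nmol / 500 uL = 0.01 nmol/uL = 10 uM
  expect_equal(deltaC(5, 0, geom), 10, tolerance = 1e-12)
  # 10 uM - (0.22 / (2*110)) * 1000 = 9 uM
  expect_equal(deltaC(5, 0.22, geom), 9, tolerance = 1e-12)
  # reverse gradient is negative
  expect_lt(deltaC(0, 1, geom), 0)
})

test_that("asymptotic penalty extrapolates a geometric tail in closed form", {
  # 8 + 4 + 2 + 1 + (1 * 0.5/0.5) = 16
  pen <- asymptoticPenalty(c(8, 4, 2, 1), A1 = 16, k = 4)
  expect_equal(as.numeric(pen), 0, tolerance = 1e-9)
  expect_equal(attr(pen, "extrapolated_total"), 16, tolerance = 1e-9)
  expect_equal(attr(pen, "ratio"), 0.5, tolerance = 1e-9)
  # doubling the target at fixed extrapolated total doubles the penalty
  pen2 <- asymptoticPenalty(c(8, 4, 2, 1), A1 = 32, k = 4)
  expect_equal(as.numeric(pen2), 16, tolerance = 1e-9)
  expect_error(asymptoticPenalty(c(1, 2, 4), 5, k = 3),
               class = "transflux_diagnostic")
  expect_error(asymptoticPenalty(c(4, 2, -1), 5, k = 3),
               class = "transflux_diagnostic")
})

test_that("inner fit recovers the five free parameters at fixed kon_b", {
  sp <- subParamsStudy()
  SB <- genTwoCompartment(sp, experimentDesign("basolateral_load", 18, 12))
  fit <- fitSubParams(SB, B1 = 18, kon_b_fixed = 0.410)
  for (nm in c("koff_b", "q_b", "kon_l", "koff_l", "q_l"))
    expect_lt(abs(fit[[nm]] / sp[[nm]] - 1), 0.10)
})

test_that("two-stage fit recovers all six parameters from paired designs", {
  sp <- subParamsStudy()
  SB <- genTwoCompartment(sp, experimentDesign("basolateral_load", 18, 12))
  SA <- genTwoCompartment(sp, experimentDesign("apical_load", 18, 12))
  fit <- fitKonbOuter(SB, SA, B1 = 18, A1 = 18)
  for (nm in c("kon_b", "koff_b", "q_b", "kon_l", "koff_l", "q_l"))
    expect_lt(abs(fit[[nm]] / sp[[nm]] - 1), 0.10)
  # the diagnostic curve is reported over the whole grid
  scan <- attr(fit, "scan")
  expect_equal(nrow(scan), 41)
  expect_true(all(is.finite(scan$penalty)))
})

test_that("permeability regression converts slope and intercept to P and M", {
  geom <- transwellGeometry()
  # exact line through the origin: rate = s * delta_c, s in (nmol/min)/uM
  dc <- seq(10, 2, length.out = 8)
  s <- 5.66 / 1000                       # 5.66 uL/min
  I_b <- s * dc * 30                     # amounts over tau = 30 min
  fl <- fluxSeries(I_b, A = seq(5, 1, length.out = 8), T_b = I_b,
                   delta_c = dc, tau = 30)
  fit <- permeabilityRegression(fl, geom)
  expect_equal(fit$slope_uL_min, 5.66, tolerance = 1e-9)
  # 5.66 uL/min over 0.6 cm^2 is numerically 5.66 mm/h
  expect_equal(fit$P_mm_h, 5.66, tolerance = 1e-9)
  expect_identical(fit$M_nmol_h_cm2, 0)
  expect_false(fit$metabolic)
  # negative intercept reads out as a metabolic areal rate
  I_b2 <- (s * dc - 0.005) * 30          # 0.005 nmol/min loss
  fl2 <- fluxSeries(I_b2, A = seq(5, 1, length.out = 8), T_b = I_b2,
                    delta_c = dc, tau = 30)
  fit2 <- permeabilityRegression(fl2, geom)
  expect_true(fit2$metabolic)
  expect_equal(fit2$M_nmol_h_cm2, 0.005 * 60 / 0.6, tolerance = 1e-9)
  expect_equal(fit2$P_mm_h, 5.66, tolerance = 1e-9)
  expect_error(permeabilityRegression(
    fluxSeries(I_b[1:2], 1:2, 1:2, dc[1:2], 30), geom),
    class = "transflux_invalid_input")
})
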