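# Diffusion-partition-metabolism barrier model: closed form, PDE
# integration, budget conservation, parameter recovery.

test_that("closed-form permeability combines layer and membrane in series", {
  # Table-style values: D*Kcell = 450 um^2/min, H*P0 = 888.3 um^2/min
  P <- closedFormP(barrierParamsStudy())
  expect_equal(P, 1.792154, tolerance = 1e-5)
  # membrane-dominated limit: P -> D*Kcell/H
  Pinf <- closedFormP(barrierParams(1.8, 250, 1e9, 0, 10))
  expect_equal(Pinf, 1.8 * 250 / 10 * 60 / 1000, tolerance = 1e-6)
  # layer-transparent limit: P -> P0
  P0lim <- closedFormP(barrierParams(1e6, 1e6, 5.33, 0, 10))
  expect_equal(P0lim, 5.33, tolerance = 1e-4)
})

test_that("apparent permeability is the standard Q/(A T dc) estimator", {
  expect_equal(apparentPermeability(1, 1, 1, 1), 10, tolerance = 1e-12)
  expect_equal(apparentPermeability(2, 1, 1, 1),
               2 * apparentPermeability(1, 1, 1, 1), tolerance = 1e-12)
  expect_equal(apparentPermeability(1, 1, 0.5, 1),
               2 * apparentPermeability(1, 1, 1, 1), tolerance = 1e-12)
  expect_error(apparentPermeability(1, 1, 1, 0),
               class = "transflux_invalid_input")
})

test_that("layer quadrature is exact for constant and linear profiles", {
  expect_identical(totalInLayer(rep(0, 50), 10, 0.6), 0)
  # uniform c0 = 100 uM over 10 um, 0.6 cm^2: 1e-4 * 0.6 * 1000 = 0.06 nmol
  expect_equal(totalInLayer(rep(100, 50), 10, 0.6), 0.06, tolerance = 1e-12)
  lin <- seq(2500, 100, length.out = 50)
  expect_equal(totalInLayer(lin, 10, 0.6),
               1e-4 * 0.6 * 10 * (2500 + 100) / 2, tolerance = 1e-12)
})

test_that("zero apical load produces a null run", {
  run <- simulateBarrier(barrierParamsStudy(), ca0 = 0,
                         schedule = samplingSchedule(4, 30))
  expect_equal(max(abs(run$J)), 0)
  expect_equal(max(abs(run$N_series)), 0)
})

test_that("steady-state flux matches the closed-form permeability", {
  # fixed reservoirs, no metabolism: after the transient the flux must be
  # P * A * (ca - cb) with P from the series formula
  bp <- barrierParams(1.8, 250, 5.33, 0, 10)
  run <- simulateBarrier(bp, schedule = samplingSchedule(times = c(60, 120)),
                         ca0 = 10, hold_reservoirs = TRUE)
  P_um_min <- closedFormP(bp) * 1000 / 60
  expected <- P_um_min * 1e-4 * 0.6 * 10          # nmol/min
  expect_lt(abs(run$J[2] / expected - 1), 0.01)
})

test_that("the total budget is conserved at every sampling time", {
  geom <- transwellGeometry()
  run <- simulateBarrier(barrierParamsStudy(), geom,
                         samplingSchedule(12, 30), ca0 = 10)
  A1 <- 10 * geom$Va / 1000
  budget <- run$ca_series * geom$Va / 1000 + run$N_series +
    run$cb_series * geom$Vb / 1000 + cumsum(run$J) + run$met_series
  expect_lt(max(abs(budget - A1)) / A1, 0.005)
})

test_that("halving both grid steps leaves the collected amounts stable", {
  coarse <- simulateBarrier(barrierParamsStudy(),
                            schedule = samplingSchedule(12, 30), ca0 = 10,
                            n_nodes = 50, dt_factor = 0.4)
  fine <- simulateBarrier(barrierParamsStudy(),
                          schedule = samplingSchedule(12, 30), ca0 = 10,
                          n_nodes = 99, dt_factor = 0.2)
  expect_lt(max(abs(fine$J - coarse$J) / coarse$J), 0.005)
})

test_that("a near-linear profile develops across the layer within minutes", {
  dev_from_linear <- function(t) {
    prof <- simulateBarrier(barrierParamsStudy(),
                            schedule = samplingSchedule(times = t),
                            ca0 = 10)$profile
    lin <- seq(prof[1], prof[length(prof)], length.out = length(prof))
    max(abs(prof - lin)) / max(prof)
  }
  devs <- vapply(c(1, 10, 30, 60), dev_from_linear, numeric(1))
  expect_true(all(diff(devs) < 0))  # transient decays monotonically
  expect_lt(devs[3], 0.03)          # near-linear by the first sampling
  expect_lt(devs[4], 0.01)
})

test_that("first-interval output rises with D, Kcell, P0 and falls with H", {
  base <- barrierParamsStudy()
  J1 <- function(p) simulateBarrier(p, schedule = samplingSchedule(3, 30),
                                    ca0 = 10)$J[1]
  j0 <- J1(base)
  expect_gt(J1(barrierParams(base$D * 2, base$Kcell, base$P0, base$M, 10)), j0)
  expect_gt(J1(barrierParams(base$D, base$Kcell * 2, base$P0, base$M, 10)), j0)
  expect_gt(J1(barrierParams(base$D, base$Kcell, base$P0 * 2, base$M, 10)), j0)
  expect_lt(J1(barrierParams(base$D, base$Kcell, base$P0, base$M, 20)), j0)
  expect_gt(j0, J1(barrierParams(base$D / 2, base$Kcell, base$P0, base$M, 10)))
})

test_that("unstable time steps are refused", {
  expect_error(simulateBarrier(barrierParamsStudy(), dt_factor = 0.6),
               class = "transflux_invalid_input")
  expect_error(simulateBarrier(barrierParamsStudy(), n_nodes = 3),
               class = "transflux_invalid_input")
})

test_that("self-recovery: fitting model-generated flux returns the truth", {
  geom <- transwellGeometry()
  truth <- barrierParamsStudy()
  run <- simulateBarrier(truth, geom, samplingSchedule(12, 30), ca0 = 10)
  # starting at the truth stays at the truth
  fit0 <- fitBarrier(run$J, H_fixed = 10, geom = geom, ca0 = 10,
                     init = truth)
  expect_lt(abs(fit0$D / truth$D - 1), 1e-4)
  expect_lt(abs(fit0$Kcell / truth$Kcell - 1), 1e-4)
  # starting at the documented default init recovers within 10%
  fit <- fitBarrier(run$J, H_fixed = 10, geom = geom, ca0 = 10)
  expect_lt(abs(fit$D / truth$D - 1), 0.10)
  expect_lt(abs(fit$Kcell / truth$Kcell - 1), 0.10)
  expect_lt(abs(fit$P0 / truth$P0 - 1), 0.10)
  expect_lt(abs(fit$M / truth$M - 1), 0.10)
})
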