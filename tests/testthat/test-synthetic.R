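# Synthetic-data generators: determinism, exactness without noise,
# qualitative shapes of the emulated experiment designs.

test_that("noise-free generators equal the forward models exactly", {
  p <- samplingParamsNoInsert()
  des <- rinse_design()
  S <- genSingleCompartment(p, des)
  expect_equal(as.numeric(S),
               forwardSimulate(p, c(18, rep(0, 11)))$S, tolerance = 1e-14)
  sp <- subParamsStudy()
  SB <- genTwoCompartment(sp, experimentDesign("basolateral_load", 18, 12))
  load <- splitInitialLoad(18, sp$r)
  expect_equal(as.numeric(SB),
               forwardSimulateSub(sp, c(load[["I1_b"]], rep(0, 11)),
                                  c(load[["I1_l"]], rep(0, 11)))$S_l,
               tolerance = 1e-14)
})

test_that("same seed reproduces, different seed varies", {
  p <- samplingParamsNoInsert()
  des <- rinse_design()
  n1 <- noiseModel("multiplicative-lognormal", cv = 0.05, seed = 7)
  n2 <- noiseModel("multiplicative-lognormal", cv = 0.05, seed = 8)
  a <- genSingleCompartment(p, des, n1)
  b <- genSingleCompartment(p, des, n1)
  c3 <- genSingleCompartment(p, des, n2)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_false(identical(as.numeric(a), as.numeric(c3)))
  # noise does not leak into the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(genSingleCompartment(p, des, n1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("rinse at no-insert parameters shows first-interval dominance", {
  S <- genSingleCompartment(samplingParamsNoInsert(), rinse_design())
  # hand recursion: S1 = 15.47, S2 = 1.85 -> ratio 8.34, 86% of the total
  expect_gt(S[1] / S[2], 8)
  expect_gt(S[1] / sum(S), 0.8)
})

test_that("degenerate sampler passes inputs straight through", {
  p0 <- subParams(0, 0, 0, 0, 0, 0)
  des <- experimentDesign("basolateral_load", 18, 12)
  S <- genTwoCompartment(p0, des)
  expect_equal(as.numeric(S), c(18, rep(0, 11)), tolerance = 1e-12)
})

test_that("apical design with geometric transfer gives a hump then decay", {
  sp <- subParamsStudy()
  SA <- genTwoCompartment(sp, experimentDesign("apical_load", 18, 12))
  pk <- which.max(SA)
  expect_true(pk >= 1 && pk <= 3)
  expect_true(all(diff(as.numeric(SA)[pk:12]) < 0))
  # the generating transmembrane series sums to the apical load at infinity
  Ib <- attr(SA, "I_b")
  expect_equal(as.numeric(asymptoticPenalty(Ib, 18, k = 5)), 0,
               tolerance = 1e-9)
})

test_that("barrier experiment composes PDE flux with the sampler", {
  bp <- barrierParamsStudy(); sp <- subParamsStudy()
  des <- experimentDesign("barrier_culture", 5, 12)
  gen <- genBarrierExperiment(bp, sp, des)
  # transparent sampler returns the PDE amounts untouched
  gen0 <- genBarrierExperiment(bp, subParams(0, 0, 0, 0, 0, 0), des)
  expect_equal(as.numeric(gen0$samples), gen0$flux$I_b, tolerance = 1e-12)
  # the cell layer delays the observable peak relative to a bare-membrane
  # apical-load design, where the first transfer interval is the largest
  bare <- genTwoCompartment(sp, experimentDesign("apical_load", 5, 12))
  expect_gt(which.max(gen$samples), which.max(attr(bare, "I_b")))
  # ground-truth flux supports end-to-end recovery
  fl <- estimateFluxes(gen$samples, sp, A1 = 5, des$geometry)
  expect_lt(max(abs(fl$I_b - gen$flux$I_b) / gen$flux$I_b), 1e-8)
})

test_that("full pipeline recovers barrier parameters from raw samples", {
  bp <- barrierParamsStudy(); sp <- subParamsStudy()
  des <- experimentDesign("barrier_culture", 5, 12)
  gen <- genBarrierExperiment(bp, sp, des)
  fl <- estimateFluxes(gen$samples, sp, A1 = 5, des$geometry)
  fit <- fitBarrier(fl, H_fixed = 10, geom = des$geometry,
                    schedule = samplingSchedule(12, 30),
                    ca0 = 5 / des$geometry$Va * 1000)
  expect_lt(abs(fit$D / bp$D - 1), 0.10)
  expect_lt(abs(fit$Kcell / bp$Kcell - 1), 0.10)
  expect_lt(abs(fit$P0 / bp$P0 - 1), 0.10)
  expect_lt(abs(fit$M / bp$M - 1), 0.10)
})

test_that("synthetic spectra round-trip through the spectro pipeline", {
  conc <- c(0.013, 0.04, 0.12, 0.36, 1.1, 3.3, 10)   # calibration ladder
  for (cal in list(calDMEM(), calHPMI())) {
    sps <- genSpectra(conc, cal, baseline_slope = 2e-4,
                      baseline_offset = 0.05)
    rec <- vapply(sps, function(s)
      concentrationFromAbsorbance(absorbanceAtWavelength(baselineCorrect(s),
                                                         cal), cal),
      numeric(1))
    expect_lt(max(abs(rec / conc - 1)), 1e-3)
    expect_true(all(vapply(sps, attr, logical(1), "in_range")))
  }
  # zero concentration on a zero baseline is a flat zero spectrum
  sp0 <- genSpectra(0, calDMEM())[[1]]
  expect_lt(max(abs(sp0$absorbance)), 1e-14)
  expect_false(attr(genSpectra(12, calDMEM())[[1]], "in_range"))
})
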