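test_that("steady-state induced voltage follows the thin-shell formula", {
  expect_equal(steadyStateTMP(1e5, 7.5e-6, 0), 1.125)
  expect_equal(steadyStateTMP(1e5, 7.5e-6, pi / 2), 0, tolerance = 1e-15)
  expect_equal(steadyStateTMP(1e6, 0.9e-6, 0), 1.35)
  expect_equal(steadyStateTMP(2e5, 6e-6, pi), -1.8)
})

test_that("pore rate matches an arbitrary-precision evaluation", {
  c0 <- EPConstants(alpha = 1e9, N0 = 1e8, q = 2.46, Vep = 0.258)
  # equilibrium and bare-membrane limits
  expect_equal(poreRate(0, c0@N0, c0), 0)
  expect_equal(poreRate(0, 0, c0), c0@alpha)
  # frozen 30-digit reference values (mpmath)
  expect_equal(poreRate(1, 0, c0), 3.34552981410291e15,
               tolerance = 1e-12)
  expect_equal(poreRate(0.5, 2e8, c0), 4.27594226213688e10,
               tolerance = 1e-12)
  # overflow guard: enormous voltages never produce NaN
  expect_false(is.nan(poreRate(1e4, 0, c0)))
  expect_false(is.nan(poreRate(1e4, 1e20, c0)))
})

test_that("pore conductivity matches the pore-geometry formula", {
  c0 <- EPConstants(sigmaPore = 0.6)
  expect_equal(epConductivity(0, 0.8e-9, c0, 7e-9), 0)
  # frozen 30-digit reference value (mpmath)
  expect_equal(epConductivity(1e13, 0.8e-9, c0, 7e-9),
               1.02276519968298e-5, tolerance = 1e-12)
  # linear in N
  expect_equal(epConductivity(2e13, 0.8e-9, c0, 7e-9),
               2 * epConductivity(1e13, 0.8e-9, c0, 7e-9))
  # auto sigmaPore requires resolution
  expect_error(epConductivity(1e13, 0.8e-9, EPConstants(), 7e-9), "auto")
})

test_that("pore radius rests at rStar and grows with voltage", {
  c0 <- EPConstants(poreDynamics = "energy_ode")
  expect_equal(poreRadiusRate(c0@rStar, 0, c0), 0, tolerance = 1e-20)
  # stable minimum: restoring drift on either side at zero voltage
  expect_lt(poreRadiusRate(2 * c0@rStar, 0, c0), 0)
  expect_gt(poreRadiusRate(0.8 * c0@rStar, 0, c0), 0)
  # monotone electrical term
  r <- 3e-9
  rates <- sapply(c(0.5, 1, 1.5), function(v) poreRadiusRate(r, v, c0))
  expect_true(all(diff(rates) > 0))
})

test_that("membrane grid conserves the sphere area exactly", {
  for (M in c(3L, 11L, 50L)) {
    g <- membraneGrid(getCell("CTC"), M)
    expect_equal(sum(g@weights), 4 * pi * getCell("CTC")@radius^2,
                 tolerance = 1e-14)
    expect_equal(g@thetas[1], 0)
    expect_equal(g@thetas[M], pi)
  }
})

test_that("zero-field run stays at the resting equilibrium", {
  cc <- EPConstants()
  res <- simulateCell(getCell("CTC"), MediumSpec(), PulseProtocol(0, 2e-6),
                      cc, M = 7L, horizon = 1e-5)
  expect_lt(max(abs(res@itv)), 1e-9)
  expect_lt(max(abs(res@poreDensity - cc@N0) / cc@N0), 1e-6)
  expect_lt(diff(range(res@sigmaEp)) / max(res@sigmaEp), 1e-6)
})

test_that("sub-threshold charging follows the Schwan first-order law", {
  cell <- getCell("CTC"); med <- MediumSpec(sigmaF = 0.0156)
  cc <- EPConstants()
  E <- 1e4   # 0.1 kV/cm: max ITV ~ 0.11 V, far below nucleation
  res <- simulateCell(cell, med, PulseProtocol(E, 2e-6), cc, M = 9L,
                      horizon = 2e-6, nPulse = 300L)
  tau <- schwanTime(cell, med)
  sel <- res@times > 5e-8            # skip the ramp
  pred <- steadyStateTMP(E, cell@radius, 0) * (1 - exp(-res@times[sel] / tau))
  expect_lt(max(abs(res@itv[sel, 1] - pred)) /
              steadyStateTMP(E, cell@radius, 0), 0.05)
  # pore density undisturbed
  expect_lt(max(abs(res@poreDensity - cc@N0) / cc@N0), 0.01)
  # with a pulse much longer than tau and a standard medium (where the
  # resting membrane leak is negligible), the steady value reaches the
  # static thin-shell formula within 1%
  medStd <- MediumSpec()
  long <- simulateCell(cell, medStd, PulseProtocol(E, 40e-6), cc, M = 3L,
                       horizon = 40e-6, nPulse = 100L)
  expect_lt(relErr(long@itv[length(long@times), 1],
                   steadyStateTMP(E, cell@radius, 0)), 0.01)
})

test_that("adaptive stiff integration agrees with a fixed-step RK4 oracle", {
  cell <- getCell("CTC")
  med <- MediumSpec(sigmaF = 0.0156)
  cc <- EPConstants(alpha = 1e13, N0 = 1e12)
  thetas <- c(0, pi / 2, pi)
  prot <- PulseProtocol(4e5, 2e-6)
  tEnd <- 2e-6
  ref <- rk4Membrane(cell, med, prot, cc, thetas, dt = 1e-10, tEnd = tEnd)
  g <- new("MembraneGrid", thetas = thetas,
           weights = rep(4 * pi * cell@radius^2 / 3, 3), radius = cell@radius)
  res <- simulateCell(cell, med, prot, cc, grid = g, horizon = tEnd,
                      rtol = 1e-8, nPulse = 200L)
  k <- length(res@times)
  expect_lt(max(relErr(res@itv[k, ], ref[, 1])), 1e-3)
  expect_lt(max(relErr(res@poreDensity[k, ], ref[, 2])), 1e-3)
})

test_that("suprathreshold voltage clamps and pores reseal monotonically", {
  configs <- list(list("CTC", c(1, 4)), list("WBC", c(4)),
                  list("PLT", c(10, 40)))
  for (cf in configs) {
    cal <- loadCalibratedConstants(cf[[1]])
    for (f in cf[[2]]) {
      res <- simulateCell(getCell(cf[[1]]), cal$medium,
                          PulseProtocol(f * 1e5, 2e-6), cal$constants,
                          M = 21L, horizon = 1e-4)
      expect_lt(max(abs(res@itv)), 1.6)
      # total pore count non-increasing once the membrane has discharged
      # (pore creation legitimately continues over ~5 tau after pulse end
      # while the induced voltage decays)
      tot <- as.vector(res@poreDensity %*% res@grid@weights)
      post <- res@times > 2e-6 + 5 * schwanTime(getCell(cf[[1]]), cal$medium)
      d <- diff(tot[post])
      expect_lt(max(d / max(tot)), 1e-6)
    }
  }
})

test_that("smaller cells charge faster under matched suprathreshold pulses", {
  calC <- loadCalibratedConstants("CTC")
  calP <- loadCalibratedConstants("PLT")
  resC <- calibratedRun("CTC", 4)
  resP <- simulateCell(getCell("PLT"), calP$medium,
                       PulseProtocol(40e5, 2e-6), calP$constants,
                       M = 21L, horizon = 8e-6)
  tC <- detectPhases(resC)@tChargeEnd
  tP <- detectPhases(resP)@tChargeEnd
  expect_lt(tP / tC, 0.25)
})

test_that("sub-threshold runs are flagged as nucleation-free", {
  cal <- loadCalibratedConstants("CTC")
  res <- simulateCell(getCell("CTC"), cal$medium, PulseProtocol(1e4, 2e-6),
                      cal$constants, M = 9L, horizon = 1e-5)
  pb <- detectPhases(res)
  expect_false(pb@detected)
  expect_true(is.na(pb@tChargeEnd))
})

test_that("summaries are recomputable from the stored series", {
  res <- calibratedRun("CTC", 4)
  s2 <- summarizeRun(res)
  expect_identical(res@summary, s2)
  # spot checks against the raw matrices
  expect_equal(s2$hyperpolarized$maxPoreDensity,
               max(res@poreDensity[, ncol(res@poreDensity)]))
  expect_equal(s2$peakSigmaEpPole,
               max(res@sigmaEp[, c(1, ncol(res@sigmaEp))]))
  # pole traces equal the corresponding node series
  tr <- poleTrace(res, "hyperpolarized")
  expect_identical(tr$itv, res@itv[, ncol(res@itv)])
})

test_that("calibration identity and self-consistency", {
  c0 <- EPConstants(alpha = 2e12)
  # zero free parameters: identity
  out <- calibrateConstants(list(list(cell = "CTC", field = 4e5,
                                      duration = 2e-6,
                                      observable = "peak_sigma_ep",
                                      value = 1e-4)),
                            free = character(0), constants = c0)
  expect_identical(out$constants, c0)

  # refit of a forward-simulated charging time recovers sigma_f within 1%
  med0 <- MediumSpec(sigmaF = 0.0125)
  fwd <- simulateCell(getCell("CTC"), med0, PulseProtocol(4e5, 2e-6),
                      c0, M = 11L, horizon = 8e-6)
  tgt <- detectPhases(fwd)@tChargeEnd
  fit <- calibrateConstants(
    list(list(cell = "CTC", field = 4e5, duration = 2e-6,
              observable = "t_charge_end", value = tgt, horizon = 8e-6)),
    free = "sigma_f", constants = c0, medium = MediumSpec(sigmaF = 0.02),
    M = 11L, nPulse = 400L)
  expect_lt(relErr(fit$medium@sigmaF, 0.0125), 0.01)
  expect_true(fit$converged)
})

test_that("calibration recovers known constants from synthetic targets", {
  cTrue <- EPConstants(alpha = 5e12)
  medTrue <- MediumSpec(sigmaF = 0.018)
  mk <- function(obs, horizon, time = NULL) {
    res <- simulateCell(getCell("CTC"), medTrue, PulseProtocol(4e5, 2e-6),
                        cTrue, M = 11L, horizon = horizon)
    v <- switch(obs,
                t_charge_end = detectPhases(res)@tChargeEnd,
                sigma_ep_at = {
                  k <- which.min(abs(res@times - time))
                  max(res@sigmaEp[k, c(1, ncol(res@sigmaEp))])
                })
    list(cell = "CTC", field = 4e5, duration = 2e-6, observable = obs,
         value = v, horizon = horizon, time = time)
  }
  # charging time pins the medium; the 1 s resealing floor pins alpha
  targets <- list(mk("t_charge_end", 8e-6), mk("sigma_ep_at", 1.0, 1.0))
  fit <- calibrateConstants(targets, free = c("sigma_f", "alpha"),
                            constants = EPConstants(alpha = 2e12),
                            medium = MediumSpec(sigmaF = 0.01),
                            M = 11L, nPulse = 400L)
  expect_lt(relErr(fit$medium@sigmaF, medTrue@sigmaF), 0.05)
  expect_lt(relErr(fit$constants@alpha, cTrue@alpha), 0.05)
  expect_lt(max(abs(fit$residuals)), 0.01)
})
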