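test_that("nominal field is voltage over gap", {
  g <- SensorGeometry()
  expect_identical(g@gap, 200e-6)
  expect_equal(fieldFromVoltage(1, g) / 100, 50)      # 50 V/cm
  expect_equal(fieldFromVoltage(25, g) / 100, 1250)   # 1250 V/cm
  expect_equal(fieldFromVoltage(0, g), 0)
  expect_error(fieldFromVoltage(-1, g))
})

test_that("Cole circuit hits its plateaus and the Debye midpoint", {
  p <- CircuitParams(r0 = 1e6, rinf = 1e5, tau = 1e-5, alphaCole = 1)
  expect_lt(Mod(circuitImpedance(1e-4, p) - 1e6) / 1e6, 1e-6)
  expect_lt(Mod(circuitImpedance(1e12, p) - 1e5) / 1e5, 1e-4)
  fc <- 1 / (2 * pi * p@tau)
  expect_equal(circuitImpedance(fc, p),
               p@rinf + (p@r0 - p@rinf) * (1 - 1i) / 2, tolerance = 1e-12)
})

test_that("Debye spectra have negative reactance peaking at fc", {
  p <- CircuitParams(r0 = 7e5, rinf = 1.5e5, tau = 3e-5)
  sp <- circuitSpectrum(p, frequency = 10^seq(2, 7, length.out = 400))
  d <- decomposeSpectrum(sp)
  expect_true(all(d$xs <= 0))
  fPeak <- d$frequency[which.max(abs(d$xs))]
  expect_lt(abs(log(fPeak / (1 / (2 * pi * p@tau)))), 0.05)
  # Pythagorean decomposition and exact reconstruction
  expect_equal(d$modZ^2, d$rs^2 + d$xs^2)
  expect_equal(complex(real = d$rs, imaginary = d$xs), sp@z)
})

test_that("decomposition is the plain complex split", {
  sp <- new("ImpedanceSpectrum", frequency = c(1e3, 1e4),
            z = c(3 + 4i, -1i), voltage = 1)
  d <- decomposeSpectrum(sp)
  expect_equal(d$modZ, c(5, 1))
  expect_equal(d$rs, c(3, 0))
  expect_equal(d$xs, c(4, -1))
})

test_that("circuit fit recovers noiseless parameters to 0.1%", {
  true <- CircuitParams(r0 = 8.2e5, rinf = 1.1e5, tau = 2.4e-5)
  sp <- circuitSpectrum(true, frequency = 10^seq(3, 6, length.out = 40))
  fit <- fitCircuit(sp, init = CircuitParams(r0 = 3e5, rinf = 5e4,
                                             tau = 1e-5))
  expect_true(fit$converged)
  expect_lt(relErr(fit$params@r0, true@r0), 1e-3)
  expect_lt(relErr(fit$params@rinf, true@rinf), 1e-3)
  expect_lt(relErr(fit$params@tau, true@tau), 1e-3)
})

test_that("circuit fit tolerates 1% noise within 5% (median over seeds)", {
  true <- CircuitParams(r0 = 8.2e5, rinf = 1.1e5, tau = 2.4e-5)
  errs <- sapply(1:50, function(s) {
    sp <- generateSyntheticSpectra(list(true), 10,
                                   frequency = 10^seq(3, 6,
                                                      length.out = 40),
                                   noiseSd = 0.01, seed = s)[[1]]
    fit <- fitCircuit(sp, init = CircuitParams(r0 = 3e5, rinf = 5e4,
                                               tau = 1e-5))
    c(relErr(fit$params@r0, true@r0), relErr(fit$params@rinf, true@rinf),
      relErr(fit$params@tau, true@tau))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
  expect_lt(median(errs[3, ]), 0.05)
})

test_that("fits require at least 8 frequency points", {
  sp <- circuitSpectrum(CircuitParams(), frequency = 10^seq(3, 6,
                                                            length.out = 7))
  expect_error(fitCircuit(sp), "8")
})

test_that("voltage series is monotone and converges at high frequency", {
  cal <- loadCalibratedConstants("WBC")
  specs <- voltageSeriesModel(c(1, 5, 10, 15, 20, 25),
                              constants = cal$constants, M = 15L)
  g <- attr(specs, "gain")
  expect_true(!is.unsorted(g))
  expect_lt(g[1], 1e-3)          # 50 V/cm: no permeabilization
  expect_gt(g[6], 0.5)           # 1250 V/cm: strong permeabilization
  f <- specs[[1]]@frequency
  modZ <- sapply(specs, function(s) Mod(s@z))
  xs <- sapply(specs, function(s) Im(s@z))
  rs <- sapply(specs, function(s) Re(s@z))
  # |Z| and Rs non-increasing, |Xs| suppressed, at every frequency
  expect_true(all(apply(modZ, 1, function(r) all(diff(r) <= 1e-9 * r[1]))))
  expect_true(all(apply(rs, 1, function(r) all(diff(r) <= 1e-9 * r[1]))))
  expect_true(all(apply(abs(xs), 1, function(r)
    all(diff(r) <= 1e-9 * max(r)))))
  # high-frequency convergence: all voltages within 2% for f >= 1e5
  hi <- f >= 1e5
  spread <- apply(modZ[hi, , drop = FALSE], 1,
                  function(r) (max(r) - min(r)) / max(r))
  expect_lt(max(spread), 0.02)
  # baseline voltage reproduces the base circuit
  expect_equal(specs[[1]]@z,
               circuitImpedance(f, CircuitParams()), tolerance = 1e-6)
})

test_that("trend statistics report ordered, tied and banded structure", {
  f <- 10^seq(3, 6, length.out = 30)
  ps <- list(CircuitParams(8e5, 1e5, 3e-5), CircuitParams(5e5, 1e5, 3e-5),
             CircuitParams(2e5, 1e5, 3e-5))
  ordered <- lapply(seq_along(ps), function(k)
    circuitSpectrum(ps[[k]], f, voltage = k))
  ts <- trendStats(ordered)
  expect_true(all(ts$perFrequency$fracModZDecreasing == 1))
  expect_true(all(ts$perFrequency$fracRsDecreasing == 1))
  expect_true(all(ts$perFrequency$fracXsSuppressed == 1))

  identical3 <- lapply(1:3, function(k)
    circuitSpectrum(ps[[1]], f, voltage = k))
  ts0 <- trendStats(identical3)
  expect_true(all(ts0$perFrequency$fracModZDecreasing == 0))

  # mid-band-only effect: tau chosen so the relaxation sits at ~30 kHz
  psMid <- list(CircuitParams(3e5, 2.8e5, 5e-6),
                CircuitParams(2.9e5, 2.8e5, 5e-6))
  mid <- lapply(1:2, function(k) circuitSpectrum(psMid[[k]], f, voltage = k))
  tsM <- trendStats(mid)
  b <- tsM$bands
  expect_gt(b$meanDropModZ[b$band == "10-100 kHz"],
            b$meanDropModZ[b$band == ">100 kHz"])
})

test_that("synthetic spectra are reproducible and carry nominal noise", {
  p <- list(CircuitParams())
  a <- generateSyntheticSpectra(p, 5, noiseSd = 0.02, seed = 7)
  b <- generateSyntheticSpectra(p, 5, noiseSd = 0.02, seed = 7)
  expect_identical(a[[1]]@z, b[[1]]@z)
  clean <- generateSyntheticSpectra(p, 5, noiseSd = 0, seed = 7)[[1]]
  expect_equal(clean@z, circuitImpedance(clean@frequency, p[[1]]))
  # empirical noise sd over many draws within 5% of nominal
  f <- 10^seq(3, 6, length.out = 20)
  draws <- generateSyntheticSpectra(rep(p, 50), rep(1, 50), frequency = f,
                                    noiseSd = 0.02, seed = 11)
  resid <- unlist(lapply(draws, function(s)
    log(Mod(s@z) / Mod(circuitImpedance(f, p[[1]])))))
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.05)
})

test_that("spectra CSV round trip preserves values and flags negative Rs", {
  path <- withr::local_tempfile(fileext = ".csv")
  ps <- list(CircuitParams(8e5, 1e5, 3e-5), CircuitParams(4e5, 1e5, 3e-5))
  specs <- lapply(1:2, function(k)
    circuitSpectrum(ps[[k]], 10^seq(3, 6, length.out = 25),
                    voltage = c(1, 25)[k]))
  writeSpectraCsv(specs, path)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "frequency_hz,voltage_v,re_z_ohm,im_z_ohm")
  back <- readSpectraCsv(path)
  expect_equal(back[[1]]@z, specs[[1]]@z, tolerance = 1e-12)
  expect_equal(attr(back, "negativeRs"), c(0L, 0L))
  # apparent negative Rs readings are accepted and counted
  art <- specs
  art[[2]]@z[3] <- complex(real = -50, imaginary = Im(art[[2]]@z[3]))
  writeSpectraCsv(art, path)
  expect_equal(attr(readSpectraCsv(path), "negativeRs"), c(0L, 1L))
})
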