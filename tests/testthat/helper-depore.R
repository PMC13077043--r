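## Shared fixtures: calibrated runs are expensive enough to cache per file.

.runCache <- new.env(parent = emptyenv())

calibratedRun <- function(name, fieldKVcm, horizon = 8e-6, M = 50L) {
  key <- sprintf("%s_%g_%g_%d", name, fieldKVcm, horizon, M)
  if (is.null(.runCache[[key]])) {
    cal <- loadCalibratedConstants(name)
    .runCache[[key]] <- simulateCell(
      getCell(name), cal$medium, PulseProtocol(fieldKVcm * 1e5, 2e-6),
      cal$constants, M = M, horizon = horizon)
  }
  .runCache[[key]]
}

## Independent fixed-step RK4 integrator over the same physics, built from
## the algebraic primitives (not from simulateCell's solver path).
rk4Membrane <- function(cell, medium, protocol, constants, thetas, dt,
                        tEnd) {
  sp <- resolveSigmaPore(constants, cell, medium)
  R <- cell@radius; dm <- cell@membraneThickness
  acc <- 1 / cell@sigmaCyto + 1 / (2 * medium@sigmaF)
  tau <- R * membraneCapacitance(cell) * acc
  gGeom <- R * acc / dm
  energy <- constants@poreDynamics == "energy_ode"
  f <- function(t, s) {
    itv <- s[, 1]; N <- pmax(s[, 2], 0); rp <- pmax(s[, 3],
                                                    constants@rStar / 4)
    sep <- epConductivity(N, rp, constants, dm, sigmaPore = sp)
    u <- steadyStateTMP(pulseValue(t, protocol), R, thetas)
    cbind((u - itv * (1 + (cell@sigmaMem0 + sep) * gGeom)) / tau,
          poreRate(itv, N, constants),
          if (energy) poreRadiusRate(rp, itv, constants) else 0)
  }
  s <- cbind(rep(0, length(thetas)), constants@N0, constants@rStar)
  t <- 0
  n <- ceiling(tEnd / dt)
  for (k in seq_len(n)) {
    k1 <- f(t, s)
    k2 <- f(t + dt / 2, s + dt / 2 * k1)
    k3 <- f(t + dt / 2, s + dt / 2 * k2)
    k4 <- f(t + dt, s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  s
}

relErr <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
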