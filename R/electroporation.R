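## electroporation_core: coupled per-node membrane ODE system.
##
## Uniform-field mode: each angular node carries (ITV, N, r_p) and obeys
##   dITV/dt = [U_ss(theta, t) - ITV * (1 + (sigma_m0 + sigma_ep) * g_geom)] / tau_m
##   dN/dt   = alpha * exp(x) * [1 - N/N0 * exp(-q x)],  x = (ITV/Vep)^2
##   dr/dt   = pore-energy advection (energy_ode mode only)
## with tau_m = R C_m (1/sigma_i + 1/(2 sigma_f)) (Schwan charging time) and
## g_geom = R (1/sigma_i + 1/(2 sigma_f)) / d_m, the spherical
## access-resistance factor that lets pore conductivity load the membrane.

#' Build an angular membrane grid
#'
#' Uniform node-centered grid in theta over `[0, pi]` with spherical-zone
#' weights (boundaries at midpoints between nodes) summing to `4 pi R^2`
#' exactly.
#'
#' @param cell a [CellSpec-class] (supplies the radius).
#' @param M number of angular nodes (default 50).
#' @return a [MembraneGrid-class].
#' @export
membraneGrid <- function(cell, M = 50L) {
  th <- seq(0, pi, length.out = M)
  bounds <- c(0, (th[-M] + th[-1]) / 2, pi)
  w <- 2 * pi * cell@radius^2 * (cos(bounds[-(M + 1)]) - cos(bounds[-1]))
  new("MembraneGrid", thetas = th, weights = w, radius = cell@radius)
}

#' Steady-state induced transmembrane voltage of a spherical cell
#'
#' `U_m = 1.5 * E * R * cos(theta)`: the static thin-shell limit for an
#' insulating membrane in a uniform field.
#'
#' @param E applied field, V/m.
#' @param R cell radius, m.
#' @param theta polar angle from the field direction, rad.
#' @return induced voltage, V (vectorized over any argument).
#' @examples
#' steadyStateTMP(1e5, 7.5e-6, 0)   # 1.125 V
#' @export
steadyStateTMP <- function(E, R, theta) 1.5 * E * R * cos(theta)

#' Pore-density creation/resealing rate
#'
#' `dN/dt = alpha * exp[(ITV/Vep)^2] * (1 - N/N0 * exp(-q (ITV/Vep)^2))`.
#' The squared voltage ratio is clamped at 700 before exponentiation to
#' avoid overflow.
#'
#' @param itv induced transmembrane voltage, V.
#' @param N current pore density, 1/m^2.
#' @param constants an [EPConstants-class].
#' @return rate, 1/(m^2 s) (vectorized).
#' @export
poreRate <- function(itv, N, constants) {
  x <- pmin((itv / constants@Vep)^2, 700)
  constants@alpha * exp(x) *
    (1 - (N / constants@N0) * exp(-constants@q * x))
}

#' Resolve the pore conductivity
#'
#' `sigmaPore = NA` in an [EPConstants-class] means "mean of cytoplasmic and
#' medium conductivity"; this helper applies that rule.
#'
#' @param constants an [EPConstants-class].
#' @param cell a [CellSpec-class].
#' @param medium a [MediumSpec-class].
#' @return pore conductivity, S/m.
#' @export
resolveSigmaPore <- function(constants, cell, medium) {
  if (is.na(constants@sigmaPore)) (cell@sigmaCyto + medium@sigmaF) / 2
  else constants@sigmaPore
}

#' Pore-mediated membrane conductivity
#'
#' `sigma_ep = N * 2 pi r_p^2 sigma_p d_m / (pi r_p + 2 d_m)`: the extra
#' membrane conductivity contributed by `N` aqueous pores per unit area of
#' radius `r_p`, including the pore access resistance.
#'
#' @param N pore density, 1/m^2.
#' @param rp pore radius, m.
#' @param constants an [EPConstants-class] (supplies `sigmaPore` unless
#'   overridden).
#' @param dM membrane thickness, m.
#' @param sigmaPore optional explicit pore conductivity, S/m; required when
#'   `constants@sigmaPore` is `NA` (auto).
#' @return conductivity, S/m (vectorized).
#' @export
epConductivity <- function(N, rp, constants, dM, sigmaPore = NULL) {
  sp <- if (!is.null(sigmaPore)) sigmaPore else constants@sigmaPore
  if (any(is.na(sp)))
    stop("sigmaPore is 'auto'; pass sigmaPore= or use resolveSigmaPore()",
         call. = FALSE)
  N * (2 * pi * rp^2 * sp * dM) / (pi * rp + 2 * dM)
}

## Steric coefficient that makes rStar the resting energy minimum:
## -2 pi gamma + 2 pi sigma_eff r* + 4 beta / r* = 0.
.stericBeta <- function(constants) {
  (2 * pi * constants@lineTension -
     2 * pi * constants@surfaceTension * constants@rStar) * constants@rStar / 4
}

#' Pore-radius drift velocity (energy mode)
#'
#' Advection of the pore radius down the pore-energy gradient:
#' electrical rim force `Fmax * ITV^2 / (1 + rH/(rp + rT))` (expanding),
#' line tension `-2 pi gamma` (contracting), effective surface tension
#' `+2 pi sigma_eff rp`, and a steric term `+4 beta (r*/rp)^4 / rp` whose
#' coefficient is fixed internally so that `r_p = rStar` is the resting
#' minimum at `ITV = 0`. The mobility prefactor is `D_p / (k_B T)`.
#'
#' @param rp pore radius, m (`rp >= rStar` in normal operation).
#' @param itv induced transmembrane voltage, V.
#' @param constants an [EPConstants-class].
#' @return radial drift, m/s (vectorized).
#' @export
poreRadiusRate <- function(rp, itv, constants) {
  beta <- .stericBeta(constants)
  fel <- constants@forceMax * itv^2 / (1 + constants@rH / (rp + constants@rT))
  f <- fel - 2 * pi * constants@lineTension +
    2 * pi * constants@surfaceTension * rp +
    (4 * beta / rp) * (constants@rStar / rp)^4
  constants@poreDiffusivity / (.KBOLTZ * constants@temperature) * f
}

## ---- the coupled simulation ------------------------------------------

.outputTimes <- function(protocol, horizon, nPulse, nPost) {
  dur <- protocol@duration
  t1 <- seq(0, min(dur, horizon), length.out = nPulse)
  ts <- t1
  if (horizon > dur) {
    tailEnd <- min(1.5 * dur, horizon)
    ts <- c(ts, seq(dur, tailEnd, length.out = max(nPulse %/% 3, 10)))
    if (horizon > tailEnd * (1 + 1e-12)) {
      ts <- c(ts, exp(seq(log(tailEnd), log(horizon), length.out = nPost)))
    }
  }
  ts <- sort(unique(ts))
  ts[c(TRUE, diff(ts) > 1e-15)]
}

#' Simulate the electroporation response of one cell
#'
#' Integrates the coupled per-node membrane system (induced voltage, pore
#' density and - in `energy_ode` mode - pore radius) through the pulse and
#' the post-pulse resealing window, using an adaptive stiff solver
#' (`deSolve::ode`, lsoda, banded Jacobian). Initial conditions are the
#' resting equilibrium: `ITV = 0`, `N = N0`, `r_p = rStar`. The model is
#' fully deterministic.
#'
#' @param cell a [CellSpec-class].
#' @param medium a [MediumSpec-class].
#' @param protocol a [PulseProtocol-class].
#' @param constants an [EPConstants-class].
#' @param grid optional [MembraneGrid-class]; default `membraneGrid(cell, M)`.
#' @param M angular nodes when `grid` is NULL (default 50).
#' @param horizon total simulated time, s (default 1 s: pulse plus a
#'   resealing second with log-spaced output). Must be >= the pulse
#'   duration.
#' @param rtol,atolITV,atolN,atolRp solver tolerances.
#' @param nPulse,nPost number of output points inside the pulse window and
#'   on the post-pulse log grid.
#' @return a [SimulationResult-class].
#' @examples
#' cal <- list(constants = EPConstants(), medium = MediumSpec())
#' res <- simulateCell(getCell("CTC"), cal$medium,
#'                     PulseProtocol(4e5, 2e-6), cal$constants,
#'                     M = 11L, horizon = 1e-5)
#' @export
simulateCell <- function(cell, medium, protocol, constants, grid = NULL,
                         M = 50L, horizon = 1.0, rtol = 1e-6,
                         atolITV = 1e-6, atolN = 1e-3, atolRp = 1e-12,
                         nPulse = 400L, nPost = 120L) {
  if (horizon < protocol@duration)
    stop("horizon must be >= the pulse duration", call. = FALSE)
  if (is.null(grid)) grid <- membraneGrid(cell, M)
  nn <- length(grid@thetas)
  costh <- cos(grid@thetas)

  R <- cell@radius
  dm <- cell@membraneThickness
  sm0 <- cell@sigmaMem0
  acc <- 1 / cell@sigmaCyto + 1 / (2 * medium@sigmaF)  # access resistivity sum
  tau <- R * membraneCapacitance(cell) * acc
  gGeom <- R * acc / dm
  sp <- resolveSigmaPore(constants, cell, medium)
  energy <- constants@poreDynamics == "energy_ode"
  rStar <- constants@rStar
  alpha <- constants@alpha; N0 <- constants@N0
  q <- constants@q; Vep <- constants@Vep

  idxI <- seq(1L, 3L * nn, by = 3L)
  idxN <- idxI + 1L
  idxR <- idxI + 2L

  deriv <- function(t, y, parms) {
    itv <- y[idxI]
    N <- pmax(y[idxN], 0)
    rp <- pmax(y[idxR], 0.25 * rStar)
    Et <- pulseValue(t, protocol)
    sep <- epConductivity(N, rp, constants, dm, sigmaPore = sp)
    dI <- (1.5 * Et * R * costh - itv * (1 + (sm0 + sep) * gGeom)) / tau
    x <- pmin((itv / Vep)^2, 700)
    dN <- alpha * exp(x) * (1 - (N / N0) * exp(-q * x))
    dy <- numeric(3L * nn)
    dy[idxI] <- dI
    dy[idxN] <- dN
    if (energy) dy[idxR] <- poreRadiusRate(rp, itv, constants)
    list(dy)
  }

  y0 <- numeric(3L * nn)
  y0[idxN] <- N0
  y0[idxR] <- rStar
  times <- .outputTimes(protocol, horizon, nPulse, nPost)
  atol <- numeric(3L * nn)
  atol[idxI] <- atolITV; atol[idxN] <- atolN; atol[idxR] <- atolRp

  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", jactype = "bandint",
                      bandup = 2L, banddown = 2L,
                      rtol = rtol, atol = atol, maxsteps = 50000L)
  if (nrow(out) < length(times)) {
    tl <- out[nrow(out), 1]
    stop(sprintf(
      "stiff solver failed at t = %.4g s (%d of %d outputs); last pole ITV = %.4g V",
      tl, nrow(out), length(times), out[nrow(out), 1 + idxI[1]]),
      call. = FALSE)
  }

  itv <- out[, 1 + idxI, drop = FALSE]
  N <- pmax(out[, 1 + idxN, drop = FALSE], 0)
  rp <- pmax(out[, 1 + idxR, drop = FALSE], 0.25 * rStar)
  sep <- epConductivity(N, rp, constants, dm, sigmaPore = sp)
  dimnames(itv) <- dimnames(N) <- dimnames(rp) <- dimnames(sep) <- NULL

  res <- new("SimulationResult", times = times, grid = grid, itv = itv,
             poreDensity = N, poreRadius = rp, sigmaEp = sep,
             cell = cell, medium = medium, protocol = protocol,
             constants = constants, summary = list())
  res@summary <- summarizeRun(res)
  res
}

#' Pole time series of a simulation
#'
#' @param result a [SimulationResult-class].
#' @param pole `"depolarized"` (theta = 0, positive ITV) or
#'   `"hyperpolarized"` (theta = pi).
#' @return data.frame with columns `t`, `itv`, `poreDensity`, `poreRadius`,
#'   `sigmaEp`.
#' @export
poleTrace <- function(result, pole = c("depolarized", "hyperpolarized")) {
  pole <- match.arg(pole)
  j <- if (pole == "depolarized") 1L else length(result@grid@thetas)
  data.frame(t = result@times, itv = result@itv[, j],
             poreDensity = result@poreDensity[, j],
             poreRadius = result@poreRadius[, j],
             sigmaEp = result@sigmaEp[, j])
}

#' Tidy long-format export of a simulation
#'
#' One row per (time, node); the schema used by the CSV writers of the
#' command-line interface.
#'
#' @param result a [SimulationResult-class].
#' @return data.frame with columns `t`, `theta`, `itv`, `pore_density`,
#'   `pore_radius`, `sigma_ep`.
#' @export
asRunData <- function(result) {
  nt <- length(result@times); nn <- length(result@grid@thetas)
  data.frame(
    t = rep(result@times, times = nn),
    theta = rep(result@grid@thetas, each = nt),
    itv = as.vector(result@itv),
    pore_density = as.vector(result@poreDensity),
    pore_radius = as.vector(result@poreRadius),
    sigma_ep = as.vector(result@sigmaEp)
  )
}

## log-linear interpolation of the first upward crossing of `series`
## through `level` on time grid `t`; NA if never crossed.
.firstCrossing <- function(t, series, level) {
  above <- series > level
  if (!any(above)) return(NA_real_)
  k <- which(above)[1]
  if (k == 1) return(t[1])
  # interpolate on log(series) where possible
  s0 <- series[k - 1]; s1 <- series[k]
  if (s0 > 0 && s1 > 0 && level > 0) {
    f <- (log(level) - log(s0)) / (log(s1) - log(s0))
  } else {
    f <- (level - s0) / (s1 - s0)
  }
  t[k - 1] + f * (t[k] - t[k - 1])
}

#' Detect electroporation phase boundaries
#'
#' Operational definitions: the charging phase ends when a pole node's pore
#' density first exceeds `chargeFactor * N0` (first appreciable pore
#' formation); the fast nucleation phase ends when the membrane-total pore
#' creation rate (area-weighted `dN/dt`) has decayed to `decayFrac` of its
#' global maximum, marking the transition to slow pore evolution.
#'
#' @param result a [SimulationResult-class] containing at least one pulse.
#' @param chargeFactor pore-density threshold factor over `N0` (default 10).
#' @param decayFrac decay fraction of the peak total nucleation rate
#'   (default 0.05).
#' @return a [PhaseBoundaries-class]; `detected = FALSE` (with NA
#'   boundaries) when the threshold is never crossed (sub-threshold field).
#' @export
detectPhases <- function(result, chargeFactor = 10, decayFrac = 0.05) {
  g <- result@grid
  nn <- length(g@thetas)
  N0 <- result@constants@N0
  t <- result@times

  poleN <- pmax(result@poreDensity[, 1], result@poreDensity[, nn])
  tCharge <- .firstCrossing(t, poleN, chargeFactor * N0)
  if (is.na(tCharge)) {
    return(new("PhaseBoundaries", tChargeEnd = NA_real_,
               tNucleationEnd = NA_real_, detected = FALSE))
  }

  rate <- poreRate(result@itv, result@poreDensity, result@constants)
  total <- as.vector(rate %*% g@weights)   # pores/s over the whole membrane
  kPeak <- which.max(total)
  level <- decayFrac * total[kPeak]
  post <- seq(kPeak, length(t))
  below <- post[total[post] < level]
  if (!length(below)) {
    tNuc <- t[length(t)]
  } else {
    k <- below[1]
    s0 <- total[k - 1]; s1 <- total[k]
    f <- if (s0 > 0 && s1 > 0) (log(s0) - log(level)) / (log(s0) - log(s1))
         else (s0 - level) / (s0 - s1)
    tNuc <- t[k - 1] + f * (t[k] - t[k - 1])
  }
  new("PhaseBoundaries", tChargeEnd = tCharge, tNucleationEnd = tNuc,
      detected = TRUE)
}

#' Summarize a simulation run
#'
#' Recomputable scalar summaries of a [SimulationResult-class]: peak ITV and
#' its time per pole, ITV at pulse end per pole, maximum pore density and
#' radius per pole, peak pore conductivity (pole and area-weighted membrane
#' mean), final conductivity at the horizon, and the post-pulse resealing
#' half-life of the total excess pore count.
#'
#' @param result a [SimulationResult-class].
#' @return named list of summaries.
#' @export
summarizeRun <- function(result) {
  t <- result@times
  nn <- ncol(result@itv)
  g <- result@grid
  dur <- result@protocol@duration
  kEnd <- which.min(abs(t - dur))

  poleStats <- function(j) {
    itv <- result@itv[, j]
    kPk <- which.max(abs(itv))
    list(peakITV = itv[kPk], tPeakITV = t[kPk],
         itvAtPulseEnd = itv[kEnd],
         maxPoreDensity = max(result@poreDensity[, j]),
         tMaxPoreDensity = t[which.max(result@poreDensity[, j])],
         maxPoreRadius = max(result@poreRadius[, j]),
         peakSigmaEp = max(result@sigmaEp[, j]))
  }

  wavg <- as.vector(result@sigmaEp %*% g@weights) / sum(g@weights)
  excess <- as.vector(pmax(result@poreDensity - result@constants@N0, 0) %*%
                        g@weights)
  half <- NA_real_
  if (any(t > dur) && excess[kEnd] > 0) {
    post <- t >= dur
    half <- .firstCrossing(t[post], -excess[post], -excess[kEnd] / 2)
    if (!is.na(half)) half <- half - dur
  }

  list(
    depolarized = poleStats(1L),
    hyperpolarized = poleStats(nn),
    peakSigmaEpPole = max(result@sigmaEp[, c(1L, nn)]),
    peakSigmaEpMean = max(wavg),
    sigmaEpFinalPole = max(result@sigmaEp[length(t), c(1L, nn)]),
    sigmaEpFinalMean = wavg[length(t)],
    resealHalfLife = half,
    horizon = t[length(t)]
  )
}

setMethod("show", "SimulationResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "SimulationResult: %s, E = %.3g kV/cm, pulse %.3g us, %d nodes, %d times\n",
    object@cell@name, object@protocol@fieldStrength / 1e5,
    object@protocol@duration * 1e6, ncol(object@itv), nrow(object@itv)))
  cat(sprintf("  pole ITV at pulse end: %+.3f / %+.3f V; peak sigma_ep (pole) %.3g S/m\n",
              s$depolarized$itvAtPulseEnd, s$hyperpolarized$itvAtPulseEnd,
              s$peakSigmaEpPole))
})

setMethod("show", "PhaseBoundaries", function(object) {
  if (object@detected)
    cat(sprintf("PhaseBoundaries: charging ends %.4g s, nucleation ends %.4g s\n",
                object@tChargeEnd, object@tNucleationEnd))
  else cat("PhaseBoundaries: no pore nucleation detected (sub-threshold)\n")
})

## ---- calibration ------------------------------------------------------

.calObservable <- function(res, observable, time = NA_real_) {
  s <- res@summary
  switch(observable,
    t_charge_end = {
      pb <- detectPhases(res)
      if (!pb@detected) 10 * res@times[length(res@times)] else pb@tChargeEnd
    },
    t_nucleation_end = {
      pb <- detectPhases(res)
      if (!pb@detected) 10 * res@times[length(res@times)] else pb@tNucleationEnd
    },
    peak_sigma_ep = s$peakSigmaEpPole,
    sigma_ep_at = {
      k <- which.min(abs(res@times - time))
      max(res@sigmaEp[k, c(1L, ncol(res@sigmaEp))])
    },
    itv_abs_at = {
      k <- which.min(abs(res@times - time))
      mean(abs(res@itv[k, c(1L, ncol(res@itv))]))
    },
    max_pore_density = max(s$depolarized$maxPoreDensity,
                           s$hyperpolarized$maxPoreDensity),
    max_pore_radius = max(s$depolarized$maxPoreRadius,
                          s$hyperpolarized$maxPoreRadius),
    stop("unknown calibration observable: ", observable, call. = FALSE)
  )
}

.applyFree <- function(constants, medium, free, vals, linkN0, n0Ratio) {
  for (i in seq_along(free)) {
    f <- free[i]; v <- vals[i]
    if (f == "sigma_f") medium@sigmaF <- v
    else slot(constants, f) <- v
  }
  if (linkN0 && !"N0" %in% free && "alpha" %in% free)
    constants@N0 <- n0Ratio * constants@alpha
  list(constants = constants, medium = medium)
}

#' Calibrate electroporation constants against target observables
#'
#' Least-squares fit (log-residuals, Levenberg-Marquardt via
#' \code{minpack.lm}) of a subset of the electroporation constants and/or
#' the medium conductivity so that simulated observables match target
#' values. Needed because the pore-rate constants and the medium are not
#' part of the cell dielectric table; a calibrated set per cell type ships
#' with the package (see [loadCalibratedConstants()]).
#'
#' Available observables: `t_charge_end`, `t_nucleation_end`,
#' `peak_sigma_ep`, `sigma_ep_at` (needs `time`), `itv_abs_at` (needs
#' `time`; mean absolute pole ITV), `max_pore_density`, `max_pore_radius`.
#'
#' @param targets list of targets, each a list with elements `cell`
#'   ([CellSpec-class] or registry name), `field` (V/m), `duration` (s),
#'   `observable`, `value`, and optionally `time` and `horizon`.
#' @param free character vector naming the free parameters: any of
#'   `"alpha"`, `"N0"`, `"q"`, `"Vep"`, `"sigmaPore"`, `"rStar"`,
#'   `"sigma_f"`. Empty `free` returns the inputs unchanged.
#' @param constants starting [EPConstants-class].
#' @param medium starting [MediumSpec-class].
#' @param lower,upper named bounds on the free parameters (natural scale);
#'   defaults span two decades around the start value.
#' @param linkN0 when `alpha` is free and `N0` is not, keep
#'   `N0 = (N0_start/alpha_start) * alpha` (preserves the resting resealing
#'   time constant). Default TRUE.
#' @param M,nPulse,nPost simulation resolution used during fitting.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return list with `constants`, `medium`, `residuals` (log sim/target),
#'   `fitted` (named free-parameter values) and `converged`.
#' @export
calibrateConstants <- function(targets, free, constants = EPConstants(),
                               medium = MediumSpec(), lower = NULL,
                               upper = NULL, linkN0 = TRUE, M = 25L,
                               nPulse = 250L, nPost = 80L,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 40, ftol = 1e-10)) {
  stopifnot(length(targets) >= 1)
  if (length(free) == 0) {
    return(list(constants = constants, medium = medium,
                residuals = numeric(0), fitted = numeric(0),
                converged = TRUE))
  }
  n0Ratio <- constants@N0 / constants@alpha
  start <- vapply(free, function(f) {
    if (f == "sigma_f") medium@sigmaF else slot(constants, f)
  }, numeric(1))
  lo <- start / 100; hi <- start * 100
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)

  evalTargets <- function(logVals) {
    par <- .applyFree(constants, medium, free, 10^logVals, linkN0, n0Ratio)
    vapply(targets, function(tg) {
      cell <- if (is.character(tg$cell)) getCell(tg$cell) else tg$cell
      horizon <- if (!is.null(tg$horizon)) tg$horizon else 4 * tg$duration
      res <- simulateCell(cell, par$medium,
                          PulseProtocol(tg$field, tg$duration),
                          par$constants, M = M, horizon = horizon,
                          nPulse = nPulse, nPost = nPost)
      .calObservable(res, tg$observable,
                     if (is.null(tg$time)) NA_real_ else tg$time)
    }, numeric(1))
  }

  resid <- function(logVals) {
    sim <- evalTargets(logVals)
    tv <- vapply(targets, function(tg) tg$value, numeric(1))
    log(pmax(sim, 1e-300)) - log(tv)
  }

  fit <- minpack.lm::nls.lm(par = log10(start), lower = log10(lo),
                            upper = log10(hi), fn = resid,
                            control = control)
  vals <- 10^fit$par
  par <- .applyFree(constants, medium, free, vals, linkN0, n0Ratio)
  list(constants = par$constants, medium = par$medium,
       residuals = fit$fvec, fitted = setNames(vals, free),
       converged = fit$info %in% 1:4)
}
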