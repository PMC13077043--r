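## impedance: Cole-type forward model of a cell suspension between plate
## electrodes, voltage-dependence through the electroporation core, trend
## statistics, circuit fitting, and a synthetic-spectra generator.

#' Construct a SensorGeometry
#' @param electrodeLength,electrodeWidth lateral dimensions, m (default
#'   600 um).
#' @param gap inter-electrode spacing, m (default 200 um).
#' @return a [SensorGeometry-class].
#' @export
SensorGeometry <- function(electrodeLength = 600e-6,
                           electrodeWidth = 600e-6, gap = 200e-6) {
  new("SensorGeometry", electrodeLength = electrodeLength,
      electrodeWidth = electrodeWidth, gap = gap)
}

#' Construct CircuitParams
#' @param r0 low-frequency plateau, Ohm.
#' @param rinf high-frequency plateau, Ohm.
#' @param tau relaxation time, s.
#' @param alphaCole Cole exponent in (0, 1]; 1 = Debye.
#' @return a [CircuitParams-class].
#' @export
CircuitParams <- function(r0 = 7e5, rinf = 1.5e5, tau = 5e-5,
                          alphaCole = 1) {
  new("CircuitParams", r0 = r0, rinf = rinf, tau = tau,
      alphaCole = alphaCole)
}

#' Nominal field between the sensor electrodes
#'
#' `E = V / d` with `d` the inter-electrode gap.
#'
#' @param V applied voltage, volts (`V >= 0`, vectorized).
#' @param geom a [SensorGeometry-class].
#' @return field, V/m.
#' @examples
#' fieldFromVoltage(25, SensorGeometry()) / 100   # 1250 V/cm
#' @export
fieldFromVoltage <- function(V, geom = SensorGeometry()) {
  stopifnot(all(V >= 0))
  V / geom@gap
}

#' Cole-type circuit impedance
#'
#' `Z(f) = Rinf + (R0 - Rinf) / (1 + (i 2 pi f tau)^alphaCole)`.
#'
#' @param f frequency, Hz (`f > 0`, vectorized).
#' @param p a [CircuitParams-class].
#' @return complex impedance, Ohm.
#' @export
circuitImpedance <- function(f, p) {
  s <- (1i * 2 * pi * f * p@tau)^p@alphaCole
  p@rinf + (p@r0 - p@rinf) / (1 + s)
}

#' Build an ImpedanceSpectrum from a circuit
#' @param p a [CircuitParams-class].
#' @param frequency frequency grid, Hz.
#' @param voltage voltage label, V.
#' @return an [ImpedanceSpectrum-class].
#' @export
circuitSpectrum <- function(p, frequency = 10^seq(3, 6, length.out = 60),
                            voltage = NA_real_) {
  new("ImpedanceSpectrum", frequency = frequency,
      z = circuitImpedance(frequency, p), voltage = voltage)
}

#' Decompose an impedance spectrum
#'
#' @param spec an [ImpedanceSpectrum-class].
#' @return data.frame with `frequency`, `modZ` (|Z|), `rs` (Re Z) and `xs`
#'   (Im Z).
#' @export
decomposeSpectrum <- function(spec) {
  data.frame(frequency = spec@frequency, modZ = Mod(spec@z),
             rs = Re(spec@z), xs = Im(spec@z))
}

setMethod("show", "ImpedanceSpectrum", function(object) {
  cat(sprintf(
    "ImpedanceSpectrum: %d points, %.3g-%.3g Hz, |Z| %.3g-%.3g Ohm%s\n",
    length(object@frequency), min(object@frequency), max(object@frequency),
    min(Mod(object@z)), max(Mod(object@z)),
    if (is.na(object@voltage)) "" else sprintf(", V = %g V", object@voltage)))
})

setMethod("show", "CircuitParams", function(object) {
  cat(sprintf(
    "CircuitParams: R0 = %.4g Ohm, Rinf = %.4g Ohm, tau = %.3g s (fc = %.3g Hz), alpha = %.3g\n",
    object@r0, object@rinf, object@tau, 1 / (2 * pi * object@tau),
    object@alphaCole))
})

#' Voltage series of suspension spectra through the electroporation core
#'
#' For each applied voltage, runs the electroporation model on a
#' representative cell at `E = V / gap` and maps the permeabilized membrane
#' conductivity at the end of the drive window onto the circuit: the
#' membrane-limited resistance `R0 - Rinf` is scaled by `1 - gain * g`
#' with `g = dsigma / (dsigma + sigma_m0)`, where `dsigma` is the pore
#' conductivity in excess of its resting value - the simplest monotone
#' link between permeabilization and suspension resistance. `g` is forced
#' non-decreasing in voltage, so `|Z|` and `Rs` are non-increasing and
#' `|Xs|` is suppressed toward zero at every frequency, while all spectra
#' share `Rinf` (high-frequency convergence). The default drive window is
#' 100 us: impedance spectroscopy applies sustained excitation, so the
#' membrane is given ample time to charge at every voltage.
#'
#' @param voltages ascending applied voltages, V.
#' @param base baseline [CircuitParams-class] (the intact suspension).
#' @param cell representative [CellSpec-class] (default: the WBC entry, a
#'   stand-in for a suspended monocytic cell).
#' @param geom a [SensorGeometry-class].
#' @param constants an [EPConstants-class].
#' @param medium a [MediumSpec-class]; the default is a physiological
#'   culture medium (`sigmaF = 1.5` S/m), the suspension the sensor
#'   actually measures, not a low-conductivity electroporation buffer.
#' @param frequency output frequency grid, Hz.
#' @param gain maximum fractional drop of the membrane-limited resistance
#'   (in (0, 1]).
#' @param duration,M,horizon electroporation-run settings.
#' @return list of [ImpedanceSpectrum-class], one per voltage, with an
#'   attribute `"gain"` holding the per-voltage `g` values.
#' @export
voltageSeriesModel <- function(voltages, base = CircuitParams(),
                               cell = getCell("WBC"),
                               geom = SensorGeometry(),
                               constants = EPConstants(),
                               medium = MediumSpec(sigmaF = 1.5),
                               frequency = 10^seq(3, 6, length.out = 60),
                               gain = 0.95, duration = 1e-4, M = 21L,
                               horizon = NULL) {
  stopifnot(!is.unsorted(voltages))
  if (is.null(horizon)) horizon <- 2 * duration
  sp <- resolveSigmaPore(constants, cell, medium)
  sepRest <- epConductivity(constants@N0, constants@rStar, constants,
                            cell@membraneThickness, sigmaPore = sp)
  g <- vapply(voltages, function(V) {
    E <- fieldFromVoltage(V, geom)
    if (E <= 0) return(0)
    res <- simulateCell(cell, medium, PulseProtocol(E, duration),
                        constants, M = M, horizon = horizon,
                        nPulse = 200L, nPost = 40L)
    kEnd <- which.min(abs(res@times - duration))
    dsep <- max(0, max(res@sigmaEp[kEnd, ]) - sepRest)
    dsep / (dsep + cell@sigmaMem0)
  }, numeric(1))
  g <- cummax(g)   # guard against solver-level non-monotonicity
  specs <- lapply(seq_along(voltages), function(k) {
    p <- new("CircuitParams", r0 = base@rinf +
               (base@r0 - base@rinf) * (1 - gain * g[k]),
             rinf = base@rinf, tau = base@tau, alphaCole = base@alphaCole)
    circuitSpectrum(p, frequency, voltage = voltages[k])
  })
  attr(specs, "gain") <- g
  specs
}

#' Fit a Cole circuit to a measured spectrum
#'
#' Weighted complex least squares over log-frequency (residuals are real
#' and imaginary parts scaled by 1/|Z|), Levenberg-Marquardt with bounded,
#' log-transformed parameters.
#'
#' @param spec an [ImpedanceSpectrum-class] with at least 8 points.
#' @param init starting [CircuitParams-class].
#' @param fitAlpha also fit the Cole exponent (default FALSE: Debye).
#' @return list with `params` ([CircuitParams-class]), `residual` (rms of
#'   the weighted residuals) and `converged`.
#' @export
fitCircuit <- function(spec, init = CircuitParams(), fitAlpha = FALSE) {
  if (length(spec@frequency) < 8)
    stop("need at least 8 frequency points to fit a circuit", call. = FALSE)
  f <- spec@frequency
  zObs <- spec@z
  w <- 1 / pmax(Mod(zObs), 1e-300)
  mk <- function(par) {
    a <- if (fitAlpha) 1 / (1 + exp(-par[4])) else init@alphaCole
    new("CircuitParams", r0 = exp(par[1]) + exp(par[2]), rinf = exp(par[2]),
        tau = exp(par[3]), alphaCole = a)
  }
  resid <- function(par) {
    zm <- circuitImpedance(f, mk(par))
    c(w * (Re(zm) - Re(zObs)), w * (Im(zm) - Im(zObs)))
  }
  par0 <- c(log(init@r0 - init@rinf), log(init@rinf), log(init@tau))
  if (fitAlpha) par0 <- c(par0, log(init@alphaCole /
                                      max(1 - init@alphaCole, 1e-6)))
  fit <- minpack.lm::nls.lm(par = par0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  list(params = mk(fit$par),
       residual = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4)
}

#' Monotonicity statistics across a voltage series
#'
#' For spectra ordered by voltage, computes per frequency the fraction of
#' adjacent voltage pairs with decreasing `|Z|`, with `|Xs|` suppressed
#' toward 0, and with decreasing `Rs`, plus band summaries over 1-10 kHz,
#' 10-100 kHz and >100 kHz.
#'
#' @param spectra list of [ImpedanceSpectrum-class] ordered by voltage, on
#'   a common frequency grid.
#' @param tol relative tolerance treating ties as "not decreasing".
#' @return list with `perFrequency` (data.frame) and `bands` (data.frame).
#' @export
trendStats <- function(spectra, tol = 1e-12) {
  stopifnot(length(spectra) >= 2)
  f <- spectra[[1]]@frequency
  for (s in spectra) stopifnot(isTRUE(all.equal(s@frequency, f)))
  zs <- vapply(spectra, function(s) s@z, complex(length(f)))
  modZ <- Mod(zs); rs <- Re(zs); xs <- Im(zs)
  nPairs <- length(spectra) - 1
  scale <- pmax(modZ[, -ncol(modZ), drop = FALSE], 1e-300)
  fracDec <- function(M) {
    d <- M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE]
    rowMeans(d < -tol * scale)
  }
  perF <- data.frame(
    frequency = f,
    fracModZDecreasing = fracDec(modZ),
    fracXsSuppressed = fracDec(abs(xs)),   # |Xs| shrinking toward 0
    fracRsDecreasing = fracDec(rs)
  )
  bands <- data.frame(
    band = c("1-10 kHz", "10-100 kHz", ">100 kHz"),
    lo = c(1e3, 1e4, 1e5), hi = c(1e4, 1e5, Inf))
  bands$fracModZDecreasing <- vapply(seq_len(3), function(b) {
    sel <- f >= bands$lo[b] & f < bands$hi[b]
    if (!any(sel)) NA_real_ else mean(perF$fracModZDecreasing[sel])
  }, numeric(1))
  bands$meanDropModZ <- vapply(seq_len(3), function(b) {
    sel <- f >= bands$lo[b] & f < bands$hi[b]
    if (!any(sel)) return(NA_real_)
    d <- (modZ[sel, 1, drop = FALSE] - modZ[sel, ncol(modZ), drop = FALSE]) /
      modZ[sel, 1, drop = FALSE]
    mean(d)
  }, numeric(1))
  list(perFrequency = perF, bands = bands[, c("band", "fracModZDecreasing",
                                              "meanDropModZ")])
}

#' Generate synthetic impedance spectra
#'
#' Forward Cole model per voltage plus multiplicative log-normal noise on
#' the complex impedance (same draw applied to modulus, phase left exact),
#' reproducible under a fixed seed. A stand-in for suspension measurements
#' when no instrument data are available.
#'
#' @param params list of [CircuitParams-class], one per voltage.
#' @param voltages voltage labels, V (same length as `params`).
#' @param frequency frequency grid, Hz.
#' @param noiseSd standard deviation of `log |Z|` noise (>= 0).
#' @param seed integer seed.
#' @return list of [ImpedanceSpectrum-class].
#' @export
generateSyntheticSpectra <- function(params, voltages,
                                     frequency = 10^seq(3, 6,
                                                        length.out = 60),
                                     noiseSd = 0.01, seed = 1L) {
  stopifnot(noiseSd >= 0, length(params) == length(voltages))
  set.seed(seed)
  lapply(seq_along(params), function(k) {
    z <- circuitImpedance(frequency, params[[k]])
    fac <- exp(stats::rnorm(length(frequency), 0, noiseSd))
    new("ImpedanceSpectrum", frequency = frequency, z = z * fac,
        voltage = voltages[k])
  })
}

## ---- CSV I/O ----------------------------------------------------------

#' Write spectra to CSV
#'
#' Dialect: header `frequency_hz,voltage_v,re_z_ohm,im_z_ohm`, UTF-8,
#' '.' decimal separator.
#'
#' @param spectra list of [ImpedanceSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectraCsv <- function(spectra, path) {
  rows <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(frequency_hz = s@frequency, voltage_v = s@voltage,
               re_z_ohm = Re(s@z), im_z_ohm = Im(s@z))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Accepts the dialect written by [writeSpectraCsv()]. Apparent negative
#' series-resistance readings (a known measurement artifact of highly
#' capacitive samples) are accepted and flagged via the attribute
#' `"negativeRs"` (count per spectrum), never rejected.
#'
#' @param path CSV path.
#' @return list of [ImpedanceSpectrum-class] ordered by voltage.
#' @export
readSpectraCsv <- function(path) {
  d <- read.csv(path)
  need <- c("frequency_hz", "voltage_v", "re_z_ohm", "im_z_ohm")
  if (!all(need %in% names(d)))
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(sort(unique(d$voltage_v)), function(v) {
    dd <- d[d$voltage_v == v, ]
    dd <- dd[order(dd$frequency_hz), ]
    new("ImpedanceSpectrum", frequency = dd$frequency_hz,
        z = complex(real = dd$re_z_ohm, imaginary = dd$im_z_ohm),
        voltage = v)
  })
  attr(out, "negativeRs") <- vapply(out, function(s) sum(Re(s@z) < 0),
                                    integer(1))
  out
}
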