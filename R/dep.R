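## dep_transport: Clausius-Mossotti spectra, DEP / traveling-wave DEP
## forces, and overdamped trajectory simulation.

.complexPerm <- function(epsRel, sigma, omega) {
  .EPS0 * epsRel - 1i * sigma / omega
}

#' Clausius-Mossotti factor of a cell
#'
#' `K = (eps_p* - eps_f*) / (eps_p* + 2 eps_f*)` with complex permittivities
#' `eps* = eps0 eps_r - i sigma / omega`. In `"single_shell"` mode (default)
#' the particle permittivity is the effective value of a membrane shell
#' over a cytoplasmic core,
#' `eps_p* = eps_m* (a^3 + 2L) / (a^3 - L)` with `a = R/(R - d_m)` and
#' `L = (eps_i* - eps_m*)/(eps_i* + 2 eps_m*)`; in `"homogeneous"` mode the
#' particle is a uniform sphere with the cytoplasmic properties (useful for
#' the textbook low/high-frequency limits).
#'
#' @param cell a [CellSpec-class].
#' @param medium a [MediumSpec-class].
#' @param omega angular frequency, rad/s (vectorized).
#' @param model `"single_shell"` or `"homogeneous"`.
#' @return complex Clausius-Mossotti factor.
#' @export
cmFactor <- function(cell, medium, omega, model = c("single_shell",
                                                    "homogeneous")) {
  model <- match.arg(model)
  ef <- .complexPerm(medium@epsF, medium@sigmaF, omega)
  ep <- if (model == "homogeneous") {
    .complexPerm(cell@epsCyto, cell@sigmaCyto, omega)
  } else {
    em <- .complexPerm(cell@epsMem, cell@sigmaMem0, omega)
    ei <- .complexPerm(cell@epsCyto, cell@sigmaCyto, omega)
    a3 <- (cell@radius / (cell@radius - cell@membraneThickness))^3
    L <- (ei - em) / (ei + 2 * em)
    em * (a3 + 2 * L) / (a3 - L)
  }
  (ep - ef) / (ep + 2 * ef)
}

#' Time-averaged dielectrophoretic force
#'
#' `F = 2 pi eps0 eps_f R^3 Re[K] grad(E^2)`.
#'
#' @param R particle radius, m.
#' @param medium a [MediumSpec-class].
#' @param reK real part of the Clausius-Mossotti factor.
#' @param gradE2 gradient of the squared field, V^2/m^3 (vector or matrix
#'   of components).
#' @return force, N (same shape as `gradE2`).
#' @examples
#' depForce(7.5e-6, MediumSpec(), 1, c(1e12, 0))
#' @export
depForce <- function(R, medium, reK, gradE2) {
  2 * pi * .EPS0 * medium@epsF * R^3 * reK * gradE2
}

#' Analytic traveling-wave field above a phased electrode array
#'
#' Phasor field of the potential wave `V0 exp(-k z) exp(-i k x)` produced by
#' a quarter-phase-shifted coplanar electrode array (wavelength
#' `lambda = 2 pi / k`, z the height above the array). Used as an in-repo
#' fixture so traveling-wave DEP is testable without a field solve.
#'
#' @param x,z evaluation coordinates, m (vectors; a grid is formed).
#' @param V0 wave amplitude, volts.
#' @param lambda spatial wavelength, m.
#' @return list with `x`, `z` and matrices `ERx`, `ERz`, `EIx`, `EIz`
#'   (real/imaginary field components, V/m; dimensions x by z).
#' @export
travelingWaveField <- function(x, z, V0 = 1, lambda = 400e-6) {
  k <- 2 * pi / lambda
  decay <- exp(-k * z)
  A <- k * V0 * outer(rep(1, length(x)), decay)
  sx <- outer(sin(k * x), rep(1, length(z)))
  cx <- outer(cos(k * x), rep(1, length(z)))
  list(x = x, z = z,
       ERx = A * sx, ERz = A * cx,
       EIx = A * cx, EIz = -A * sx)
}

#' Traveling-wave DEP force field
#'
#' `F = 2 pi eps0 eps_f R^3 [ Re(K) grad(E^2) + 2 Im(K) curl(E_I x E_R) ]`
#' evaluated by centered finite differences on a gridded complex field
#' `E = E_R + i E_I` (components in the x-z plane, no y dependence). With
#' `Im(K) = 0` or `E_I = 0` this reduces exactly to the plain DEP force.
#'
#' @param R particle radius, m.
#' @param medium a [MediumSpec-class].
#' @param K complex Clausius-Mossotti factor.
#' @param field list as returned by [travelingWaveField()]: `x`, `z`,
#'   `ERx`, `ERz`, `EIx`, `EIz`.
#' @return list with force-component matrices `Fx`, `Fz` (N).
#' @export
twdepForce <- function(R, medium, K, field) {
  hx <- field$x[2] - field$x[1]
  hz <- field$z[2] - field$z[1]
  E2 <- field$ERx^2 + field$ERz^2 + field$EIx^2 + field$EIz^2
  Q <- field$EIz * field$ERx - field$EIx * field$ERz  # (E_I x E_R)_y
  pref <- 2 * pi * .EPS0 * medium@epsF * R^3
  Fx <- pref * (Re(K) * .gradAlong(E2, hx, 1L) +
                  2 * Im(K) * (-.gradAlong(Q, hz, 2L)))
  Fz <- pref * (Re(K) * .gradAlong(E2, hz, 2L) +
                  2 * Im(K) * .gradAlong(Q, hx, 1L))
  list(Fx = Fx, Fz = Fz)
}

#' Clausius-Mossotti spectrum with crossover frequencies
#'
#' Evaluates [cmFactor()] on a log-spaced frequency grid and refines every
#' sign change of `Re[K]` by bisection.
#'
#' @param cell a [CellSpec-class].
#' @param medium a [MediumSpec-class].
#' @param fMin,fMax frequency range, Hz.
#' @param n grid points.
#' @param model passed to [cmFactor()].
#' @return a [DEPSpectrum-class]; `crossovers` holds the refined roots
#'   (rad/s).
#' @export
cmSpectrum <- function(cell, medium, fMin = 1e3, fMax = 1e9, n = 400L,
                       model = "single_shell") {
  stopifnot(fMin > 0, fMax > fMin)
  omega <- 2 * pi * exp(seq(log(fMin), log(fMax), length.out = n))
  K <- cmFactor(cell, medium, omega, model = model)
  reK <- Re(K)
  cross <- numeric(0)
  s <- sign(reK)
  idx <- which(s[-1] * s[-n] < 0)
  for (k in idx) {
    root <- uniroot(function(w) Re(cmFactor(cell, medium, w, model = model)),
                    lower = omega[k], upper = omega[k + 1], tol = 1e-6)
    cross <- c(cross, root$root)
  }
  new("DEPSpectrum", omega = omega, reK = reK, imK = Im(K),
      crossovers = cross)
}

setMethod("show", "DEPSpectrum", function(object) {
  cat(sprintf(
    "DEPSpectrum: %d points, %.3g-%.3g Hz, Re[K] in [%.3f, %.3f], %d crossover(s)\n",
    length(object@omega), min(object@omega) / (2 * pi),
    max(object@omega) / (2 * pi), min(object@reK), max(object@reK),
    length(object@crossovers)))
  if (length(object@crossovers))
    cat("  crossovers at", paste(sprintf("%.4g Hz",
        object@crossovers / (2 * pi)), collapse = ", "), "\n")
})

#' Overdamped DEP trajectory of a single cell
#'
#' Inertialess (Stokes) dynamics: `v = F_DEP / (6 pi eta R) + v_flow`,
#' integrated with explicit Euler. The particle counts as trapped when its
#' total speed stays below `trapSpeed` for `trapSteps` consecutive steps
#' (it has come to rest at a field extremum); it exits when it leaves
#' `bounds` (path truncated, `exited` flag).
#'
#' @param cell a [CellSpec-class].
#' @param medium a [MediumSpec-class].
#' @param reK real Clausius-Mossotti factor at the drive frequency.
#' @param gradE2 function `(xz) -> c(gx, gz)`, V^2/m^3.
#' @param start initial position `c(x, z)`, m.
#' @param dt time step, s.
#' @param tEnd end time, s.
#' @param flow optional function `(xz) -> c(vx, vz)`, m/s.
#' @param bounds `c(xmin, xmax, zmin, zmax)`, m.
#' @param trapSpeed,trapSteps trapping criterion (default 1 um/s over 100
#'   steps).
#' @return a [Trajectory-class].
#' @export
simulateTrajectory <- function(cell, medium, reK, gradE2, start, dt, tEnd,
                               flow = NULL, bounds = c(-Inf, Inf, -Inf, Inf),
                               trapSpeed = 1e-6, trapSteps = 100L) {
  R <- cell@radius
  drag <- 6 * pi * medium@viscosity * R
  nSteps <- ceiling(tEnd / dt)
  pos <- matrix(NA_real_, nSteps + 1, 2)
  vel <- matrix(NA_real_, nSteps + 1, 2)
  pos[1, ] <- start
  slowRun <- 0L
  trapped <- FALSE
  exited <- FALSE
  n <- nSteps + 1
  for (k in seq_len(nSteps)) {
    p <- pos[k, ]
    F <- depForce(R, medium, reK, gradE2(p))
    v <- F / drag
    if (!is.null(flow)) v <- v + flow(p)
    vel[k, ] <- v
    slowRun <- if (sqrt(sum(v^2)) < trapSpeed) slowRun + 1L else 0L
    if (slowRun >= trapSteps) { trapped <- TRUE; n <- k; break }
    pNew <- p + dt * v
    if (pNew[1] < bounds[1] || pNew[1] > bounds[2] ||
        pNew[2] < bounds[3] || pNew[2] > bounds[4]) {
      exited <- TRUE; n <- k; break
    }
    pos[k + 1, ] <- pNew
  }
  if (is.na(vel[n, 1])) {
    p <- pos[n, ]
    F <- depForce(R, medium, reK, gradE2(p))
    v <- F / drag
    if (!is.null(flow)) v <- v + flow(p)
    vel[n, ] <- v
  }
  new("Trajectory", times = (seq_len(n) - 1) * dt,
      position = pos[seq_len(n), , drop = FALSE],
      velocity = vel[seq_len(n), , drop = FALSE],
      trapped = trapped,
      trapLocation = if (trapped) pos[n, ] else c(NA_real_, NA_real_),
      exited = exited)
}

setMethod("show", "Trajectory", function(object) {
  state <- if (object@trapped) sprintf("trapped at (%.3g, %.3g) m",
                                       object@trapLocation[1],
                                       object@trapLocation[2])
           else if (object@exited) "exited the domain"
           else "ran to tEnd"
  cat(sprintf("Trajectory: %d steps, %s\n", nrow(object@position) - 1, state))
})
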