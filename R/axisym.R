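## pulse_field, high-fidelity path: steady axisymmetric conduction solve
## with the membrane as a contact-impedance interface.
##
## Domain: cylindrical (rho, z), symmetry axis at rho = 0, plate electrodes
## at z = -zMax (potential +U/2) and z = +zMax (-U/2), insulating outer
## wall. A spherical cell may sit centered at the origin. The nm-scale
## membrane is never meshed: grid faces crossing the sphere surface get a
## series conductance containing the term d_m / (sigma_m0 + sigma_ep(theta)),
## the discrete form of the distributed-impedance membrane condition.

#' Construct an AxisymGeometry
#'
#' Defaults describe a 50 um electrode gap with 100 um wide electrodes
#' (domain radius 50 um).
#'
#' @param rhoMax radial domain size, m.
#' @param zMax half of the electrode gap, m.
#' @param nRho,nZ grid nodes in rho and z.
#' @return an [AxisymGeometry-class].
#' @export
AxisymGeometry <- function(rhoMax = 50e-6, zMax = 25e-6,
                           nRho = 200L, nZ = 200L) {
  new("AxisymGeometry", rhoMax = rhoMax, zMax = zMax,
      nRho = as.integer(nRho), nZ = as.integer(nZ))
}

## node conductivity/permittivity maps; theta measured from +z
.axisymMaps <- function(geom, cell, medium, membrane) {
  rho <- seq(0, geom@rhoMax, length.out = geom@nRho)
  z <- seq(-geom@zMax, geom@zMax, length.out = geom@nZ)
  rr <- outer(rho^2, z^2, "+")   # nRho x nZ squared distance from center
  inside <- if (is.null(cell)) matrix(FALSE, geom@nRho, geom@nZ)
            else rr < cell@radius^2
  sig <- matrix(medium@sigmaF, geom@nRho, geom@nZ)
  eps <- matrix(medium@epsF, geom@nRho, geom@nZ)
  if (!is.null(cell)) {
    sig[inside] <- cell@sigmaCyto
    eps[inside] <- cell@epsCyto
  }
  list(rho = rho, z = z, inside = inside, sig = sig, eps = eps)
}

#' Solve the axisymmetric conduction problem around a cell
#'
#' Finite-volume (5-point) discretization of
#' `div(sigma grad V) = 0` on a cylindrical grid, with the cell membrane as
#' a contact-impedance interface: any grid face crossing the sphere surface
#' carries the series conductance of the adjacent half-cells plus
#' `d_m / (sigma_m0 + sigma_ep(theta))`. The electrodes are plates at
#' `z = -zMax` (+U/2) and `z = +zMax` (-U/2), so the nominal field is
#' `U / (2 zMax)` pointing along +z; theta is measured from +z.
#'
#' @param geom an [AxisymGeometry-class].
#' @param cell a [CellSpec-class], or NULL for a homogeneous domain.
#' @param medium a [MediumSpec-class].
#' @param sigmaEp pore conductivity on the membrane, S/m: a single number,
#'   a function of theta, or NULL (no electroporation).
#' @param appliedV total potential difference across the gap, volts.
#' @param membrane FALSE replaces the membrane interface by direct
#'   cytoplasm/medium contact (a plain conducting sphere).
#' @return a [PotentialField-class].
#' @examples
#' f <- solveAxisymPotential(AxisymGeometry(nRho = 60, nZ = 60),
#'                           cell = NULL, medium = MediumSpec(),
#'                           appliedV = 1)
#' @export
solveAxisymPotential <- function(geom, cell, medium, sigmaEp = NULL,
                                 appliedV = 1, membrane = TRUE) {
  mp <- .axisymMaps(geom, cell, medium, membrane)
  nR <- geom@nRho; nZ <- geom@nZ
  rho <- mp$rho; z <- mp$z
  hR <- rho[2] - rho[1]; hZ <- z[2] - z[1]
  R <- if (is.null(cell)) -1 else cell@radius
  if (!is.null(cell)) {
    if (hR > R / 4 || hZ > R / 4)
      warning("grid barely resolves the cell; refine nRho/nZ", call. = FALSE)
  }
  sigEpFun <- if (is.null(sigmaEp)) function(th) 0
    else if (is.function(sigmaEp)) sigmaEp
    else function(th) rep_len(sigmaEp, length(th))

  id <- function(i, j) (j - 1L) * nR + i
  nUnk <- nR * nZ

  ## face conductance between two nodes a distance h apart, cross-section A;
  ## crossing tells whether the sphere surface lies between them.
  faceG <- function(sA, sB, inA, inB, A, h, thFace) {
    g <- numeric(length(sA))
    crossing <- membrane & (inA != inB)
    plain <- !crossing
    g[plain] <- A[plain] / (h / 2 / sA[plain] + h / 2 / sB[plain])
    if (any(crossing)) {
      sm <- cell@sigmaMem0 + sigEpFun(thFace[crossing])
      memTerm <- ifelse(sm > 0, cell@membraneThickness / sm, Inf)
      g[crossing] <- A[crossing] /
        (h / 2 / sA[crossing] + h / 2 / sB[crossing] + memTerm)
    }
    g
  }

  ## assemble triplets
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  bb <- numeric(nUnk)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }

  ## radial faces between (i, j) and (i+1, j), i = 1..nR-1
  iA <- rep(1:(nR - 1L), nZ); jA <- rep(1:nZ, each = nR - 1L)
  kA <- id(iA, jA); kB <- id(iA + 1L, jA)
  rhoFace <- (rho[iA] + rho[iA + 1L]) / 2
  Aface <- 2 * pi * rhoFace * hZ
  thFace <- atan2(rhoFace, z[jA])
  gR <- faceG(mp$sig[cbind(iA, jA)], mp$sig[cbind(iA + 1L, jA)],
              mp$inside[cbind(iA, jA)], mp$inside[cbind(iA + 1L, jA)],
              Aface, hR, thFace)

  ## axial faces between (i, j) and (i, j+1), j = 1..nZ-1
  iC <- rep(1:nR, nZ - 1L); jC <- rep(1:(nZ - 1L), each = nR)
  kC <- id(iC, jC); kD <- id(iC, jC + 1L)
  zFace <- (z[jC] + z[jC + 1L]) / 2
  Az <- ifelse(iC == 1L, pi * (hR / 2)^2,
               2 * pi * rho[iC] * ifelse(iC == nR, hR / 2, hR))
  thFaceZ <- atan2(rho[iC], zFace)
  gZ <- faceG(mp$sig[cbind(iC, jC)], mp$sig[cbind(iC, jC + 1L)],
              mp$inside[cbind(iC, jC)], mp$inside[cbind(iC, jC + 1L)],
              Az, hZ, thFaceZ)

  dirichlet <- logical(nUnk)
  dirichlet[id(1:nR, 1L)] <- TRUE          # z = -zMax: +U/2
  dirichlet[id(1:nR, nZ)] <- TRUE          # z = +zMax: -U/2
  vDir <- numeric(nUnk)
  vDir[id(1:nR, 1L)] <- appliedV / 2
  vDir[id(1:nR, nZ)] <- -appliedV / 2

  addFace <- function(ka, kb, g) {
    free_a <- !dirichlet[ka]; free_b <- !dirichlet[kb]
    # row ka: +g on (ka,ka), -g on (ka,kb)
    add(ka[free_a], ka[free_a], g[free_a])
    w <- free_a & free_b
    add(ka[w], kb[w], -g[w])
    bb[ka[free_a & !free_b]] <<- bb[ka[free_a & !free_b]] +
      g[free_a & !free_b] * vDir[kb[free_a & !free_b]]
    # row kb symmetric
    add(kb[free_b], kb[free_b], g[free_b])
    add(kb[w], ka[w], -g[w])
    bb[kb[free_b & !free_a]] <<- bb[kb[free_b & !free_a]] +
      g[free_b & !free_a] * vDir[ka[free_b & !free_a]]
  }
  addFace(kA, kB, gR)
  addFace(kC, kD, gZ)
  dd <- which(dirichlet)
  add(dd, dd, rep(1, length(dd)))
  bb[dd] <- vDir[dd]

  Amat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = c(nUnk, nUnk))
  sol <- tryCatch(Matrix::solve(Amat, bb),
                  error = function(e) stop(
                    "linear solve failed: ", conditionMessage(e),
                    call. = FALSE))
  resid <- sqrt(sum((as.vector(Amat %*% sol) - bb)^2)) /
    max(sqrt(sum(bb^2)), 1e-300)
  if (resid > 1e-8)
    stop(sprintf("conduction solve did not converge (relative residual %.3g)",
                 resid), call. = FALSE)
  V <- matrix(as.numeric(sol), nR, nZ)

  ## central-difference fields (one-sided at the borders)
  Erho <- -.gradAlong(V, hR, 1L)
  Ez <- -.gradAlong(V, hZ, 2L)
  Drho <- .EPS0 * mp$eps * Erho
  Dz <- .EPS0 * mp$eps * Ez
  new("PotentialField", rho = rho, z = z, V = V, Erho = Erho, Ez = Ez,
      Drho = Drho, Dz = Dz, geometry = geom)
}

.grad1 <- function(v, h) {
  n <- length(v)
  g <- numeric(n)
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  g[1] <- (v[2] - v[1]) / h
  g[n] <- (v[n] - v[n - 1]) / h
  g
}

.gradAlong <- function(M, h, dim) {
  if (dim == 1L) apply(M, 2, .grad1, h = h)
  else t(apply(M, 1, .grad1, h = h))
}

#' Displacement field from a solved potential
#'
#' `D = eps0 * eps_r * E` pointwise. The permittivity map defaults to the
#' cell/medium layout of the solve; pass `epsMap` (matrix matching the
#' grid, or a single number) to override.
#'
#' @param field a [PotentialField-class].
#' @param epsMap optional relative-permittivity override.
#' @return list with components `Drho`, `Dz` (C/m^2) and `norm`.
#' @export
displacementField <- function(field, epsMap = NULL) {
  if (is.null(epsMap)) {
    Drho <- field@Drho; Dz <- field@Dz
  } else {
    Drho <- .EPS0 * epsMap * field@Erho
    Dz <- .EPS0 * epsMap * field@Ez
  }
  list(Drho = Drho, Dz = Dz, norm = sqrt(Drho^2 + Dz^2))
}

#' Extract the induced transmembrane voltage from an axisymmetric solution
#'
#' Samples the potential on radial rays just inside and just outside the
#' membrane and extrapolates both linearly onto the sphere surface;
#' `ITV(theta) = V_in - V_out` with theta measured from +z (the nominal
#' field direction).
#'
#' @param field a [PotentialField-class] solved with a cell present.
#' @param cell the [CellSpec-class] used in the solve.
#' @param thetas angles at which to sample, rad (default 49 values in
#'   `[0, pi]`).
#' @return data.frame with columns `theta` and `itv`.
#' @export
extractITV <- function(field, cell, thetas = seq(0, pi, length.out = 49)) {
  h <- max(field@rho[2] - field@rho[1], field@z[2] - field@z[1])
  R <- cell@radius
  sample2 <- function(r) {
    rho <- r * sin(thetas); zz <- r * cos(thetas)
    .bilinear(field@rho, field@z, field@V, rho, zz)
  }
  d1 <- 1.5 * h; d2 <- 3 * h
  vin <- sample2(R - d1) + (sample2(R - d1) - sample2(R - d2)) * d1 / (d2 - d1)
  vout <- sample2(R + d1) + (sample2(R + d1) - sample2(R + d2)) * d1 / (d2 - d1)
  data.frame(theta = thetas, itv = vin - vout)
}

.bilinear <- function(xg, yg, M, x, y) {
  hx <- xg[2] - xg[1]; hy <- yg[2] - yg[1]
  ix <- pmin(pmax(floor((x - xg[1]) / hx) + 1, 1), length(xg) - 1)
  iy <- pmin(pmax(floor((y - yg[1]) / hy) + 1, 1), length(yg) - 1)
  fx <- (x - xg[ix]) / hx; fy <- (y - yg[iy]) / hy
  M[cbind(ix, iy)] * (1 - fx) * (1 - fy) +
    M[cbind(ix + 1, iy)] * fx * (1 - fy) +
    M[cbind(ix, iy + 1)] * (1 - fx) * fy +
    M[cbind(ix + 1, iy + 1)] * fx * fy
}

#' Total axial current through a z-plane
#'
#' Diagnostic for discrete charge conservation: in steady state the current
#' through any horizontal plane is the same.
#'
#' @param field a [PotentialField-class].
#' @param cell the cell used in the solve (NULL for homogeneous domains).
#' @param medium the [MediumSpec-class] used.
#' @param zPlane z position between grid rows, m.
#' @param sigmaEp,membrane as passed to [solveAxisymPotential()].
#' @return current, A.
#' @export
planeCurrent <- function(field, cell, medium, zPlane, sigmaEp = NULL,
                         membrane = TRUE) {
  geom <- field@geometry
  mp <- .axisymMaps(geom, cell, medium, membrane)
  z <- field@z; rho <- field@rho
  hZ <- z[2] - z[1]; hR <- rho[2] - rho[1]
  j <- findInterval(zPlane, z)
  j <- min(max(j, 1L), length(z) - 1L)
  sigEpFun <- if (is.null(sigmaEp)) function(th) 0
    else if (is.function(sigmaEp)) sigmaEp
    else function(th) rep_len(sigmaEp, length(th))
  nR <- geom@nRho
  iC <- 1:nR
  zFace <- (z[j] + z[j + 1]) / 2
  Az <- ifelse(iC == 1L, pi * (hR / 2)^2,
               2 * pi * rho[iC] * ifelse(iC == nR, hR / 2, hR))
  sA <- mp$sig[cbind(iC, j)]; sB <- mp$sig[cbind(iC, j + 1)]
  inA <- mp$inside[cbind(iC, j)]; inB <- mp$inside[cbind(iC, j + 1)]
  th <- atan2(rho[iC], zFace)
  g <- numeric(nR)
  crossing <- membrane & (inA != inB) & !is.null(cell)
  plain <- !crossing
  g[plain] <- Az[plain] / (hZ / 2 / sA[plain] + hZ / 2 / sB[plain])
  if (any(crossing)) {
    sm <- cell@sigmaMem0 + sigEpFun(th[crossing])
    g[crossing] <- Az[crossing] /
      (hZ / 2 / sA[crossing] + hZ / 2 / sB[crossing] +
         ifelse(sm > 0, cell@membraneThickness / sm, Inf))
  }
  sum(g * (field@V[, j] - field@V[, j + 1]))
}
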