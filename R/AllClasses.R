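#' @import methods
#' @importFrom stats approx optimize uniroot median setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

## Physical constants used throughout (SI)
.EPS0 <- 8.854e-12      # vacuum permittivity, F/m
.KBOLTZ <- 1.380649e-23 # Boltzmann constant, J/K

#' CellSpec: dielectric description of one spherical cell type
#'
#' Holds the geometric and dielectric parameters of a single spherical cell:
#' radius, membrane thickness, cytoplasmic and (resting) membrane
#' conductivities, and relative permittivities of cytoplasm and membrane.
#' The built-in registry (see [getCell()]) ships entries for circulating
#' tumor cells (`"CTC"`), white blood cells (`"WBC"`) and platelets
#' (`"PLT"`).
#'
#' @slot name character label.
#' @slot radius cell radius, m.
#' @slot membraneThickness membrane thickness d_m, m.
#' @slot sigmaCyto cytoplasmic conductivity, S/m.
#' @slot sigmaMem0 resting membrane conductivity, S/m.
#' @slot epsCyto relative permittivity of the cytoplasm (dimensionless).
#' @slot epsMem relative permittivity of the membrane (dimensionless).
#' @export
setClass("CellSpec",
  representation(
    name = "character",
    radius = "numeric",
    membraneThickness = "numeric",
    sigmaCyto = "numeric",
    sigmaMem0 = "numeric",
    epsCyto = "numeric",
    epsMem = "numeric"
  )
)

setValidity("CellSpec", function(object) {
  v <- c(radius = object@radius, d_m = object@membraneThickness,
         sigma_i = object@sigmaCyto, sigma_m = object@sigmaMem0,
         eps_i = object@epsCyto, eps_m = object@epsMem)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all cell parameters must be finite and positive")
  if (object@radius / object@membraneThickness <= 10)
    return("thin-shell assumption violated: radius must exceed 10x membrane thickness")
  TRUE
})

#' MediumSpec: suspending-medium properties
#'
#' @slot sigmaF medium conductivity, S/m.
#' @slot epsF relative permittivity of the medium (dimensionless).
#' @slot viscosity dynamic viscosity, Pa s (used for Stokes drag).
#' @slot eps0 vacuum permittivity, fixed at 8.854e-12 F/m.
#' @export
setClass("MediumSpec",
  representation(
    sigmaF = "numeric",
    epsF = "numeric",
    viscosity = "numeric",
    eps0 = "numeric"
  ),
  prototype(eps0 = .EPS0)
)

setValidity("MediumSpec", function(object) {
  if (any(c(object@sigmaF, object@epsF, object@viscosity) <= 0))
    return("medium parameters must be positive")
  if (abs(object@eps0 - .EPS0) > 1e-18)
    return("eps0 is a physical constant and must equal 8.854e-12 F/m")
  TRUE
})

#' PulseProtocol: excitation waveform description
#'
#' A rectangular (smoothed Heaviside) or sinusoidal excitation of given field
#' strength and duration. The rectangular pulse rises over `riseTime` with a
#' tanh ramp (C1-smooth, as required by stiff integrators); the ideal step is
#' the `riseTime -> 0` limit and the half-rise point carries value E/2.
#'
#' @slot fieldStrength applied field magnitude E, V/m.
#' @slot duration pulse duration, s.
#' @slot riseTime ramp time of the smoothed step, s (must be < duration/10).
#' @slot waveform `"rect_heaviside"` or `"sine"`.
#' @slot frequency sine frequency, Hz (ignored for rectangular pulses).
#' @export
setClass("PulseProtocol",
  representation(
    fieldStrength = "numeric",
    duration = "numeric",
    riseTime = "numeric",
    waveform = "character",
    frequency = "numeric"
  )
)

setValidity("PulseProtocol", function(object) {
  if (object@duration <= 0) return("duration must be positive")
  if (object@fieldStrength < 0) return("fieldStrength must be non-negative")
  if (object@riseTime <= 0 || object@riseTime >= object@duration / 10)
    return("riseTime must be positive and smaller than duration/10")
  if (!object@waveform %in% c("rect_heaviside", "sine"))
    return("waveform must be 'rect_heaviside' or 'sine'")
  if (object@waveform == "sine" && (length(object@frequency) != 1 || object@frequency <= 0))
    return("sine waveform requires a positive frequency")
  TRUE
})

#' EPConstants: electroporation-model constants
#'
#' Constants of the pore-density rate equation, the pore conductivity formula
#' and (optionally) the pore-radius energy dynamics. `sigmaPore = NA` means
#' "use the mean of cytoplasmic and medium conductivity", resolved at
#' simulation time. `N0` is the resting equilibrium pore density; it is
#' exposed as a calibration knob (see [calibrateConstants()]), and the
#' default couples it to `alpha` through a 0.1 s resting resealing time
#' constant (`N0 = 0.1 * alpha`), a sub-second membrane-recovery time scale.
#'
#' @slot alpha pore creation rate, 1/(m^2 s).
#' @slot N0 equilibrium pore density, 1/m^2.
#' @slot q sealing exponent (dimensionless).
#' @slot Vep characteristic electroporation voltage, V (within (0.1, 1.0)).
#' @slot sigmaPore conductivity of the pore interior, S/m (NA = auto).
#' @slot rStar minimum / initial pore radius, m.
#' @slot poreDynamics `"fixed_radius"` or `"energy_ode"`.
#' @slot poreDiffusivity pore-radius diffusivity D_p, m^2/s (energy mode).
#' @slot forceMax maximum electrical force on the pore rim per volt squared,
#'   N/V^2 (energy mode).
#' @slot rH,rT force-saturation length scales, m (energy mode).
#' @slot lineTension pore edge line tension, N (energy mode).
#' @slot surfaceTension effective membrane surface tension, N/m (energy mode;
#'   default 0, i.e. a floppy membrane whose pores reseal).
#' @slot temperature absolute temperature, K.
#' @export
setClass("EPConstants",
  representation(
    alpha = "numeric",
    N0 = "numeric",
    q = "numeric",
    Vep = "numeric",
    sigmaPore = "numeric",
    rStar = "numeric",
    poreDynamics = "character",
    poreDiffusivity = "numeric",
    forceMax = "numeric",
    rH = "numeric",
    rT = "numeric",
    lineTension = "numeric",
    surfaceTension = "numeric",
    temperature = "numeric"
  )
)

setValidity("EPConstants", function(object) {
  pos <- c(object@alpha, object@N0, object@q, object@Vep, object@rStar,
           object@poreDiffusivity, object@forceMax, object@rH, object@rT,
           object@lineTension, object@temperature)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all electroporation constants must be finite and positive")
  if (!is.na(object@sigmaPore) && object@sigmaPore <= 0)
    return("sigmaPore must be positive (or NA for the sigma_i/sigma_f mean)")
  if (object@surfaceTension < 0) return("surfaceTension must be >= 0")
  if (object@Vep <= 0.1 || object@Vep >= 1.0)
    return("Vep must lie in (0.1, 1.0) V")
  if (!object@poreDynamics %in% c("fixed_radius", "energy_ode"))
    return("poreDynamics must be 'fixed_radius' or 'energy_ode'")
  TRUE
})

#' MembraneGrid: angular discretization of the membrane
#'
#' Node-centered angular grid over the polar angle theta in `[0, pi]` with
#' spherical-zone area weights that sum to the full sphere area `4 pi R^2`
#' exactly. The first node (theta = 0) faces the field vector (depolarized
#' pole, positive induced voltage); the last (theta = pi) is the
#' hyperpolarized pole.
#'
#' @slot thetas node angles, rad, increasing from 0 to pi.
#' @slot weights node zone areas, m^2.
#' @slot radius cell radius the weights refer to, m.
#' @export
setClass("MembraneGrid",
  representation(thetas = "numeric", weights = "numeric", radius = "numeric")
)

setValidity("MembraneGrid", function(object) {
  th <- object@thetas
  if (length(th) < 2 || is.unsorted(th, strictly = TRUE))
    return("thetas must be strictly increasing with at least 2 nodes")
  if (abs(th[1]) > 1e-12 || abs(th[length(th)] - pi) > 1e-12)
    return("grid must span [0, pi] with nodes at both poles")
  A <- 4 * pi * object@radius^2
  if (abs(sum(object@weights) - A) > 1e-9 * A)
    return("area weights must sum to 4*pi*R^2")
  TRUE
})

#' SimulationResult: full state history of one electroporation run
#'
#' Time-resolved per-node membrane state (induced transmembrane voltage,
#' pore density, pore radius, pore-mediated membrane conductivity) together
#' with the inputs that produced it and a summary block.
#'
#' @slot times output time grid, s.
#' @slot grid the [MembraneGrid-class] used.
#' @slot itv matrix (time x node) of induced transmembrane voltage, V.
#' @slot poreDensity matrix (time x node) of pore density, 1/m^2.
#' @slot poreRadius matrix (time x node) of pore radius, m.
#' @slot sigmaEp matrix (time x node) of pore conductivity, S/m.
#' @slot cell,medium,protocol,constants the simulation inputs.
#' @slot summary list produced by [summarizeRun()].
#' @export
setClass("SimulationResult",
  representation(
    times = "numeric",
    grid = "MembraneGrid",
    itv = "matrix",
    poreDensity = "matrix",
    poreRadius = "matrix",
    sigmaEp = "matrix",
    cell = "CellSpec",
    medium = "MediumSpec",
    protocol = "PulseProtocol",
    constants = "EPConstants",
    summary = "list"
  )
)

setValidity("SimulationResult", function(object) {
  nt <- length(object@times); nn <- length(object@grid@thetas)
  for (nm in c("itv", "poreDensity", "poreRadius", "sigmaEp")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(nt, nn)))
      return(sprintf("slot '%s' must be a %d x %d matrix", nm, nt, nn))
  }
  if (any(object@poreDensity < 0)) return("pore density must be non-negative")
  TRUE
})

#' PhaseBoundaries: operational electroporation phase boundaries
#'
#' @slot tChargeEnd end of the charging phase, s (NA if never reached).
#' @slot tNucleationEnd end of the fast nucleation phase, s (NA if absent).
#' @slot detected TRUE when pore nucleation occurred.
#' @export
setClass("PhaseBoundaries",
  representation(tChargeEnd = "numeric", tNucleationEnd = "numeric",
                 detected = "logical")
)

setValidity("PhaseBoundaries", function(object) {
  if (object@detected) {
    if (!is.finite(object@tChargeEnd) || !is.finite(object@tNucleationEnd))
      return("detected boundaries must be finite")
    if (!(0 < object@tChargeEnd && object@tChargeEnd < object@tNucleationEnd))
      return("need 0 < tChargeEnd < tNucleationEnd")
  }
  TRUE
})

#' DEPSpectrum: Clausius-Mossotti factor over frequency
#'
#' @slot omega angular frequency grid, rad/s (increasing).
#' @slot reK,imK real and imaginary part of the Clausius-Mossotti factor.
#' @slot crossovers frequencies (rad/s) where Re K changes sign.
#' @export
setClass("DEPSpectrum",
  representation(omega = "numeric", reK = "numeric", imK = "numeric",
                 crossovers = "numeric")
)

setValidity("DEPSpectrum", function(object) {
  if (is.unsorted(object@omega, strictly = TRUE))
    return("omega must be strictly increasing")
  if (length(object@reK) != length(object@omega) ||
      length(object@imK) != length(object@omega))
    return("reK/imK must match the omega grid")
  if (any(object@reK < -0.5 - 1e-9) || any(object@reK > 1 + 1e-9))
    return("Re[K] outside the physical bound [-0.5, 1]")
  TRUE
})

#' Trajectory: overdamped particle path in a DEP field
#'
#' @slot times time stamps, s.
#' @slot position n x 2 matrix of (x, z) positions, m.
#' @slot velocity n x 2 matrix of velocities, m/s.
#' @slot trapped TRUE if the particle came to rest near a field extremum.
#' @slot trapLocation (x, z) of the trap, m (NA if not trapped).
#' @slot exited TRUE if the particle left the channel (path truncated).
#' @export
setClass("Trajectory",
  representation(times = "numeric", position = "matrix", velocity = "matrix",
                 trapped = "logical", trapLocation = "numeric",
                 exited = "logical")
)

#' ImpedanceSpectrum: complex impedance over frequency at one drive voltage
#'
#' @slot frequency frequency grid, Hz, strictly increasing.
#' @slot z complex impedance, Ohm.
#' @slot voltage applied voltage label, V.
#' @export
setClass("ImpedanceSpectrum",
  representation(frequency = "numeric", z = "complex", voltage = "numeric")
)

setValidity("ImpedanceSpectrum", function(object) {
  if (is.unsorted(object@frequency, strictly = TRUE))
    return("frequency must be strictly increasing")
  if (length(object@z) != length(object@frequency))
    return("z must match the frequency grid")
  TRUE
})

#' CircuitParams: Cole-type relaxation circuit for a cell suspension
#'
#' Z(f) = Rinf + (R0 - Rinf) / (1 + (i 2 pi f tau)^alphaCole).
#' `alphaCole = 1` is the Debye (single time constant) case. R0 is the
#' low-frequency plateau, dominated by the insulating membranes of intact
#' cells; Rinf the high-frequency plateau where current bypasses the
#' membrane capacitively; tau the relaxation time (membrane-capacitance
#' interpretation: tau ~ (R0 - Rinf) * C_membrane of the suspension).
#'
#' @slot r0 low-frequency resistance plateau, Ohm.
#' @slot rinf high-frequency resistance plateau, Ohm.
#' @slot tau relaxation time, s.
#' @slot alphaCole Cole broadening exponent in (0, 1].
#' @export
setClass("CircuitParams",
  representation(r0 = "numeric", rinf = "numeric", tau = "numeric",
                 alphaCole = "numeric")
)

setValidity("CircuitParams", function(object) {
  if (!(object@r0 > object@rinf && object@rinf > 0))
    return("need r0 > rinf > 0")
  if (object@tau <= 0) return("tau must be positive")
  if (object@alphaCole <= 0 || object@alphaCole > 1)
    return("alphaCole must lie in (0, 1]")
  TRUE
})

#' SensorGeometry: impedance-sensor electrode geometry
#'
#' Defaults match a microfabricated sensor with 600 um square electrodes
#' separated by a 200 um gap; the nominal field is E = V / gap.
#'
#' @slot electrodeLength,electrodeWidth lateral electrode dimensions, m.
#' @slot gap inter-electrode spacing d, m.
#' @export
setClass("SensorGeometry",
  representation(electrodeLength = "numeric", electrodeWidth = "numeric",
                 gap = "numeric")
)

setValidity("SensorGeometry", function(object) {
  if (any(c(object@electrodeLength, object@electrodeWidth, object@gap) <= 0))
    return("sensor dimensions must be positive")
  TRUE
})

#' AxisymGeometry: domain for the axisymmetric conduction solve
#'
#' Cylindrical (rho, z) domain with plate electrodes at z = +/- zMax
#' (electrode gap = 2 zMax) and a symmetry axis at rho = 0. The cell sits
#' centered on the axis at z = 0.
#'
#' @slot rhoMax radial half-width of the domain, m.
#' @slot zMax axial half-height; electrodes at +/- zMax, m.
#' @slot nRho,nZ number of grid nodes in rho and z.
#' @export
setClass("AxisymGeometry",
  representation(rhoMax = "numeric", zMax = "numeric",
                 nRho = "integer", nZ = "integer")
)

setValidity("AxisymGeometry", function(object) {
  if (object@rhoMax <= 0 || object@zMax <= 0) return("domain must be positive")
  if (object@nRho < 10 || object@nZ < 10) return("grid too coarse (need >= 10 nodes)")
  TRUE
})

#' PotentialField: solution of the axisymmetric conduction problem
#'
#' @slot rho,z grid coordinates, m.
#' @slot V potential matrix (nRho x nZ), volts.
#' @slot Erho,Ez electric-field components, V/m.
#' @slot Drho,Dz displacement-field components, C/m^2.
#' @slot geometry the [AxisymGeometry-class] solved on.
#' @export
setClass("PotentialField",
  representation(rho = "numeric", z = "numeric", V = "matrix",
                 Erho = "matrix", Ez = "matrix",
                 Drho = "matrix", Dz = "matrix",
                 geometry = "AxisymGeometry")
)
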