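## params: typed registry of cell, medium, pulse and electroporation constants.

#' Construct a CellSpec
#'
#' @param name label for the cell type.
#' @param radius cell radius, m.
#' @param membraneThickness membrane thickness, m.
#' @param sigmaCyto cytoplasmic conductivity, S/m.
#' @param sigmaMem0 resting membrane conductivity, S/m.
#' @param epsCyto relative permittivity of the cytoplasm.
#' @param epsMem relative permittivity of the membrane.
#' @return a [CellSpec-class] object.
#' @examples
#' ctc <- CellSpec("CTC", radius = 7.5e-6, membraneThickness = 7e-9,
#'                 sigmaCyto = 1.0, sigmaMem0 = 9e-7,
#'                 epsCyto = 50, epsMem = 12.5)
#' @export
CellSpec <- function(name, radius, membraneThickness, sigmaCyto, sigmaMem0,
                     epsCyto, epsMem) {
  new("CellSpec", name = name, radius = radius,
      membraneThickness = membraneThickness, sigmaCyto = sigmaCyto,
      sigmaMem0 = sigmaMem0, epsCyto = epsCyto, epsMem = epsMem)
}

#' Construct a MediumSpec
#'
#' Defaults describe a typical low-conductivity electroporation buffer.
#'
#' @param sigmaF medium conductivity, S/m.
#' @param epsF relative permittivity of the medium.
#' @param viscosity dynamic viscosity, Pa s.
#' @return a [MediumSpec-class] object.
#' @export
MediumSpec <- function(sigmaF = 0.1, epsF = 80, viscosity = 1.0e-3) {
  new("MediumSpec", sigmaF = sigmaF, epsF = epsF, viscosity = viscosity,
      eps0 = .EPS0)
}

#' Construct a PulseProtocol
#'
#' @param fieldStrength applied field magnitude E, V/m.
#' @param duration pulse duration, s.
#' @param riseTime tanh ramp time of the smoothed step, s.
#' @param waveform `"rect_heaviside"` (default) or `"sine"`.
#' @param frequency sine frequency, Hz (sine waveform only).
#' @return a [PulseProtocol-class] object.
#' @export
PulseProtocol <- function(fieldStrength, duration, riseTime = 1e-8,
                          waveform = "rect_heaviside", frequency = NA_real_) {
  new("PulseProtocol", fieldStrength = fieldStrength, duration = duration,
      riseTime = riseTime, waveform = waveform, frequency = frequency)
}

#' Construct an EPConstants set
#'
#' Defaults follow the asymptotic electroporation literature:
#' `alpha = 1e9` pores/(m^2 s), `q = 2.46`, `Vep = 0.258` V, minimum pore
#' radius `rStar = 0.8` nm. `N0` defaults to `0.1 * alpha` so that the
#' resting resealing time constant `N0 / alpha` equals 0.1 s, a typical
#' membrane-recovery time scale; it is the main calibration knob.
#' The energy-mode pore-radius constants (`poreDiffusivity`, `forceMax`,
#' `rH`, `rT`, `lineTension`) are standard pore-energy values; the
#' steric-repulsion coefficient is derived internally from the requirement
#' that `rStar` be the resting energy minimum.
#'
#' @param alpha pore creation rate, 1/(m^2 s).
#' @param N0 equilibrium pore density, 1/m^2 (default `0.1 * alpha`).
#' @param q sealing exponent.
#' @param Vep characteristic electroporation voltage, V.
#' @param sigmaPore pore conductivity, S/m; `NA` (default) resolves to the
#'   mean of cytoplasmic and medium conductivity at simulation time.
#' @param rStar minimum pore radius, m.
#' @param poreDynamics `"fixed_radius"` (default) or `"energy_ode"`.
#' @param poreDiffusivity pore-radius diffusivity, m^2/s.
#' @param forceMax electrical force on the pore rim per V^2, N/V^2.
#' @param rH,rT force-saturation lengths, m.
#' @param lineTension pore edge tension, N.
#' @param surfaceTension effective membrane tension, N/m.
#' @param temperature absolute temperature, K.
#' @return an [EPConstants-class] object.
#' @export
EPConstants <- function(alpha = 1e9, N0 = 0.1 * alpha, q = 2.46, Vep = 0.258,
                        sigmaPore = NA_real_, rStar = 0.8e-9,
                        poreDynamics = "fixed_radius",
                        poreDiffusivity = 5e-14, forceMax = 0.70e-9,
                        rH = 0.97e-9, rT = 0.31e-9, lineTension = 1.8e-11,
                        surfaceTension = 0, temperature = 298.15) {
  new("EPConstants", alpha = alpha, N0 = N0, q = q, Vep = Vep,
      sigmaPore = sigmaPore, rStar = rStar, poreDynamics = poreDynamics,
      poreDiffusivity = poreDiffusivity, forceMax = forceMax, rH = rH,
      rT = rT, lineTension = lineTension, surfaceTension = surfaceTension,
      temperature = temperature)
}

## Built-in registry. Diameters 15 / 12 / 1.8 um, membrane 7 / 7 / 8 nm.
.cellRegistry <- function() {
  list(
    CTC = CellSpec("CTC", radius = 15e-6 / 2, membraneThickness = 7e-9,
                   sigmaCyto = 1.0, sigmaMem0 = 9e-7,
                   epsCyto = 50, epsMem = 12.5),
    WBC = CellSpec("WBC", radius = 12e-6 / 2, membraneThickness = 7e-9,
                   sigmaCyto = 0.18, sigmaMem0 = 9e-6,
                   epsCyto = 80, epsMem = 10),
    PLT = CellSpec("PLT", radius = 1.8e-6 / 2, membraneThickness = 8e-9,
                   sigmaCyto = 0.25, sigmaMem0 = 1e-6,
                   epsCyto = 50, epsMem = 6)
  )
}

#' Look up a cell type in the registry
#'
#' @param name one of `"CTC"`, `"WBC"`, `"PLT"`, or a key of `registry`.
#' @param registry optional named list of [CellSpec-class] objects replacing
#'   the built-in table (e.g. loaded from a YAML config).
#' @return the matching [CellSpec-class]; unknown names raise an error that
#'   lists the valid keys.
#' @examples
#' getCell("CTC")@radius        # 7.5e-6
#' getCell("PLT")@epsMem        # 6
#' @export
getCell <- function(name, registry = NULL) {
  reg <- if (is.null(registry)) .cellRegistry() else registry
  if (!name %in% names(reg)) {
    stop(sprintf("unknown cell type '%s'; valid keys: {%s}", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]
}

#' List registered cell types
#' @param registry optional registry list (defaults to the built-in one).
#' @return character vector of cell names.
#' @export
listCells <- function(registry = NULL) {
  names(if (is.null(registry)) .cellRegistry() else registry)
}

#' Specific membrane capacitance
#'
#' `C_m = eps_m * eps0 / d_m`, the capacitance per unit membrane area used
#' in charging-time diagnostics.
#'
#' @param cell a [CellSpec-class].
#' @return capacitance per area, F/m^2.
#' @examples
#' membraneCapacitance(getCell("CTC"))   # ~1.581e-2 F/m^2
#' @export
membraneCapacitance <- function(cell) {
  cell@epsMem * .EPS0 / cell@membraneThickness
}

#' Schwan membrane charging time constant
#'
#' First-order polarization time of a spherical cell,
#' `tau = R * C_m * (1/sigma_i + 1/(2 sigma_f))`.
#'
#' @param cell a [CellSpec-class].
#' @param medium a [MediumSpec-class].
#' @return time constant, s.
#' @export
schwanTime <- function(cell, medium) {
  cell@radius * membraneCapacitance(cell) *
    (1 / cell@sigmaCyto + 1 / (2 * medium@sigmaF))
}

## ---- config (YAML) serialization -------------------------------------

.cellToList <- function(cell) {
  list(name = cell@name, radius = cell@radius,
       membrane_thickness = cell@membraneThickness,
       sigma_cyto = cell@sigmaCyto, sigma_mem0 = cell@sigmaMem0,
       eps_cyto = cell@epsCyto, eps_mem = cell@epsMem)
}

.cellFromList <- function(x) {
  CellSpec(x$name, x$radius, x$membrane_thickness, x$sigma_cyto,
           x$sigma_mem0, x$eps_cyto, x$eps_mem)
}

.epToList <- function(c) {
  list(alpha = c@alpha, N0 = c@N0, q = c@q, Vep = c@Vep,
       sigma_pore = if (is.na(c@sigmaPore)) "auto" else c@sigmaPore,
       r_star = c@rStar, pore_dynamics = c@poreDynamics,
       pore_diffusivity = c@poreDiffusivity, force_max = c@forceMax,
       r_h = c@rH, r_t = c@rT, line_tension = c@lineTension,
       surface_tension = c@surfaceTension, temperature = c@temperature)
}

.epFromList <- function(x) {
  sp <- x$sigma_pore
  if (is.character(sp) && identical(sp, "auto")) sp <- NA_real_
  EPConstants(alpha = x$alpha, N0 = x$N0, q = x$q, Vep = x$Vep,
              sigmaPore = sp, rStar = x$r_star,
              poreDynamics = x$pore_dynamics,
              poreDiffusivity = x$pore_diffusivity, forceMax = x$force_max,
              rH = x$r_h, rT = x$r_t, lineTension = x$line_tension,
              surfaceTension = x$surface_tension,
              temperature = x$temperature)
}

#' Write a parameter registry to a YAML config file
#'
#' Serializes cells, medium and electroporation constants into the config
#' schema understood by [readParams()] and the command-line interface.
#'
#' @param path output file path.
#' @param cells named list of [CellSpec-class] (default: built-in registry).
#' @param medium a [MediumSpec-class].
#' @param epConstants an [EPConstants-class].
#' @return `path`, invisibly.
#' @export
writeParams <- function(path, cells = .cellRegistry(),
                        medium = MediumSpec(), epConstants = EPConstants()) {
  obj <- list(
    cells = lapply(unname(cells), .cellToList),
    medium = list(sigma_f = medium@sigmaF, eps_f = medium@epsF,
                  viscosity = medium@viscosity),
    ep_constants = .epToList(epConstants)
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a parameter registry from a YAML config file
#'
#' @param path YAML file written by [writeParams()] (or hand-authored with
#'   the same `cells` / `medium` / `ep_constants` blocks).
#' @return list with elements `cells` (named list of [CellSpec-class]),
#'   `medium` ([MediumSpec-class]) and `epConstants` ([EPConstants-class]).
#' @export
readParams <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("cells", "medium", "ep_constants")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cells <- lapply(x$cells, .cellFromList)
  names(cells) <- vapply(cells, function(z) z@name, character(1))
  med <- if (is.null(x$medium)) MediumSpec() else
    MediumSpec(sigmaF = x$medium$sigma_f, epsF = x$medium$eps_f,
               viscosity = x$medium$viscosity)
  epc <- if (is.null(x$ep_constants)) EPConstants() else
    .epFromList(x$ep_constants)
  list(cells = cells, medium = med, epConstants = epc)
}

#' Load the bundled paper-calibrated constants for a cell type
#'
#' The package ships, per cell type, an electroporation-constant set and a
#' medium conductivity obtained with [calibrateConstants()] against two
#' printed observables per cell type (charging time / peak conductivity for
#' CTC, pole voltage / peak pore density for WBC, charging time / peak pore
#' radius for PLT). Platelet constants use `poreDynamics = "energy_ode"`.
#'
#' @param name `"CTC"`, `"WBC"` or `"PLT"`.
#' @return list with elements `constants` ([EPConstants-class]) and
#'   `medium` ([MediumSpec-class]).
#' @export
loadCalibratedConstants <- function(name) {
  path <- system.file("extdata", "calibrated-constants.yaml",
                      package = "DEPore", mustWork = TRUE)
  x <- yaml::read_yaml(path)
  if (!name %in% names(x))
    stop(sprintf("no calibrated constants for '%s'; available: {%s}", name,
                 paste(names(x), collapse = ", ")), call. = FALSE)
  e <- x[[name]]
  list(constants = .epFromList(e$ep_constants),
       medium = MediumSpec(sigmaF = e$medium$sigma_f,
                           epsF = e$medium$eps_f,
                           viscosity = e$medium$viscosity))
}

## ---- show methods ----------------------------------------------------

setMethod("show", "CellSpec", function(object) {
  cat(sprintf(
    "CellSpec '%s': R = %.3g um, d_m = %.3g nm\n  sigma_i = %.3g S/m, sigma_m = %.3g S/m, eps_i = %.3g, eps_m = %.3g\n",
    object@name, object@radius * 1e6, object@membraneThickness * 1e9,
    object@sigmaCyto, object@sigmaMem0, object@epsCyto, object@epsMem))
})

setMethod("show", "MediumSpec", function(object) {
  cat(sprintf("MediumSpec: sigma_f = %.3g S/m, eps_f = %.3g, eta = %.3g Pa s\n",
              object@sigmaF, object@epsF, object@viscosity))
})

setMethod("show", "PulseProtocol", function(object) {
  cat(sprintf("PulseProtocol: %s, E = %.4g V/m (%.4g kV/cm), duration %.3g s, rise %.3g s\n",
              object@waveform, object@fieldStrength,
              object@fieldStrength / 1e5, object@duration, object@riseTime))
})

setMethod("show", "EPConstants", function(object) {
  cat(sprintf(
    "EPConstants: alpha = %.3g /m^2/s, N0 = %.3g /m^2, q = %.3g, Vep = %.3g V\n  sigma_p = %s, r* = %.3g nm, pore dynamics: %s\n",
    object@alpha, object@N0, object@q, object@Vep,
    if (is.na(object@sigmaPore)) "auto (mean of sigma_i, sigma_f)"
    else sprintf("%.3g S/m", object@sigmaPore),
    object@rStar * 1e9, object@poreDynamics))
})
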