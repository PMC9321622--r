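#' @include AllGenerics.R
NULL

.SPECTRUM_KINDS <- c("emission", "absorbance", "molar_absorptivity",
                     "ellipticity", "ftir")

#' Spectrum: a one-dimensional spectral trace
#'
#' Container for a single spectral trace: an ordered axis (wavelength in
#' nm for UV-Vis / fluorescence / CD, wavenumber in cm^-1 for FTIR) and
#' the corresponding signal. The axis is always stored strictly
#' increasing; traces recorded in decreasing order (common for FTIR) are
#' reversed on construction and the original orientation noted in the
#' label.
#'
#' @slot axis numeric, strictly increasing, length >= 2
#' @slot signal numeric, same length as `axis`
#' @slot kind character, one of `"emission"`, `"absorbance"`,
#'   `"molar_absorptivity"`, `"ellipticity"`, `"ftir"`.
#'   Absorbance-like kinds must be non-negative.
#' @slot label free-text provenance tag
#'
#' @examples
#' s <- Spectrum(seq(300, 400, 5), dnorm(seq(300, 400, 5), 330, 20),
#'               kind = "emission")
#' peakOf(s)
#' @export
setClass("Spectrum",
  representation(axis = "numeric", signal = "numeric",
                 kind = "character", label = "character"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@axis) != length(object@signal))
    msg <- c(msg, "axis and signal lengths differ")
  if (length(object@axis) < 2)
    msg <- c(msg, "a Spectrum needs at least 2 points")
  if (anyNA(object@axis) || anyNA(object@signal))
    msg <- c(msg, "axis/signal must be finite")
  else if (any(diff(object@axis) <= 0))
    msg <- c(msg, "axis must be strictly increasing")
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
    msg <- c(msg, paste("kind must be one of:",
                        paste(.SPECTRUM_KINDS, collapse = ", ")))
  else if (object@kind %in% c("absorbance", "molar_absorptivity") &&
           any(object@signal < 0))
    msg <- c(msg, paste(object@kind, "signal must be >= 0"))
  if (length(msg)) msg else TRUE
})

#' @param axis,signal,kind,label see slots
#' @rdname Spectrum-class
#' @export
Spectrum <- function(axis, signal, kind = "emission", label = "") {
  axis <- as.numeric(axis); signal <- as.numeric(signal)
  if (length(axis) >= 2 && !is.unsorted(rev(axis), strictly = TRUE)) {
    # stored decreasing: normalize, keep a note of the original order
    axis <- rev(axis); signal <- rev(signal)
    label <- if (nzchar(label)) paste0(label, " [axis reversed on load]")
             else "[axis reversed on load]"
  }
  new("Spectrum", axis = axis, signal = signal, kind = kind, label = label)
}

#' @rdname accessors
#' @export
setMethod("axisValues", "Spectrum", function(x) x@axis)
#' @rdname accessors
#' @export
setMethod("signalValues", "Spectrum", function(x) x@signal)
#' @rdname accessors
#' @export
setMethod("spectrumKind", "Spectrum", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("spectrumLabel", "Spectrum", function(x) x@label)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, axis %.4g..%.4g%s\n",
              object@kind, length(object@axis),
              min(object@axis), max(object@axis),
              if (nzchar(object@label)) paste0(" | ", object@label) else ""))
})

#' @rdname Spectrum-class
#' @param x a Spectrum
#' @export
setMethod("length", "Spectrum", function(x) length(x@axis))

#' EEMatrix: an excitation-emission matrix
#'
#' Three-dimensional fluorescence landscape: intensity indexed by
#' excitation wavelength (rows) and emission wavelength (columns).
#'
#' @slot excitation numeric, strictly increasing excitation axis (nm)
#' @slot emission numeric, strictly increasing emission axis (nm)
#' @slot intensity numeric matrix, `length(excitation)` x `length(emission)`
#' @export
setClass("EEMatrix",
  representation(excitation = "numeric", emission = "numeric",
                 intensity = "matrix"))

setValidity("EEMatrix", function(object) {
  msg <- character()
  if (nrow(object@intensity) != length(object@excitation) ||
      ncol(object@intensity) != length(object@emission))
    msg <- c(msg, "intensity dimensions must match the two axes")
  if (!all(is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (any(diff(object@excitation) <= 0) || any(diff(object@emission) <= 0))
    msg <- c(msg, "axes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @param excitation,emission,intensity see slots
#' @rdname EEMatrix-class
#' @export
EEMatrix <- function(excitation, emission, intensity) {
  new("EEMatrix", excitation = as.numeric(excitation),
      emission = as.numeric(emission),
      intensity = as.matrix(intensity))
}

setMethod("show", "EEMatrix", function(object) {
  cat(sprintf("EEMatrix: %d excitation x %d emission (ex %g..%g, em %g..%g nm)\n",
              length(object@excitation), length(object@emission),
              min(object@excitation), max(object@excitation),
              min(object@emission), max(object@emission)))
})

#' TitrationSeries: a fluorescence quenching titration
#'
#' Quencher concentrations and fluorescence intensities at a fixed
#' temperature and emission read-out. `F0` is the unquenched intensity
#' (at zero quencher); the concentration vector may itself start at 0,
#' in which case that point's intensity should equal `F0` up to noise.
#'
#' @slot concentration mol/L, non-negative, strictly increasing
#' @slot intensity a.u., positive, same length
#' @slot F0 unquenched intensity (a.u.), positive
#' @slot temperature K
#' @slot readOut emission read-out, e.g. `"peak"` or `"327 nm"`
#' @export
setClass("TitrationSeries",
  representation(concentration = "numeric", intensity = "numeric",
                 F0 = "numeric", temperature = "numeric",
                 readOut = "character"))

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@concentration) != length(object@intensity))
    msg <- c(msg, "concentration and intensity lengths differ")
  if (any(object@intensity <= 0)) msg <- c(msg, "intensities must be > 0")
  if (length(object@F0) != 1L || object@F0 <= 0)
    msg <- c(msg, "F0 must be a single positive value")
  if (any(object@concentration < 0) ||
      any(diff(object@concentration) <= 0))
    msg <- c(msg, "concentrations must be non-negative, strictly increasing")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (K)")
  if (length(msg)) msg else TRUE
})

#' @param concentration,intensity,F0,temperature,readOut see slots
#' @rdname TitrationSeries-class
#' @export
TitrationSeries <- function(concentration, intensity, F0 = NULL,
                            temperature = 298, readOut = "peak") {
  concentration <- as.numeric(concentration)
  intensity <- as.numeric(intensity)
  if (is.null(F0)) {
    if (length(concentration) && concentration[1] == 0) F0 <- intensity[1]
    else stop("F0 must be given when the series has no zero-concentration point")
  }
  new("TitrationSeries", concentration = concentration,
      intensity = intensity, F0 = as.numeric(F0),
      temperature = as.numeric(temperature), readOut = readOut)
}

#' @rdname accessors
#' @export
setMethod("temperature", "TitrationSeries", function(x) x@temperature)

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries: %d points, [Q] %.3g..%.3g M, F0 = %.4g, T = %g K (%s)\n",
    length(object@concentration), min(object@concentration),
    max(object@concentration), object@F0, object@temperature,
    object@readOut))
})

#' QuenchFit: a Stern-Volmer fit
#'
#' Result of the Stern-Volmer regression F0/F = 1 + Ksv [Q]. `kq` is the
#' bimolecular quenching rate constant Ksv / tau0.
#'
#' @slot ksv Stern-Volmer constant (L/mol)
#' @slot kq quenching rate constant (L/mol/s), = ksv / tau0 exactly
#' @slot tau0 unquenched fluorophore lifetime (s)
#' @slot intercept fitted intercept (dimensionless; 1 for ideal data)
#' @slot r Pearson correlation of F0/F with [Q]
#' @slot sd standard error of the slope (Ksv)
#' @slot temperature K
#' @slot nPoints points used in the regression
#' @export
setClass("QuenchFit",
  representation(ksv = "numeric", kq = "numeric", tau0 = "numeric",
                 intercept = "numeric", r = "numeric", sd = "numeric",
                 temperature = "numeric", nPoints = "integer"))

setValidity("QuenchFit", function(object) {
  msg <- character()
  if (abs(object@kq - object@ksv / object@tau0) >
      1e-9 * max(1, abs(object@kq)))
    msg <- c(msg, "kq must equal ksv / tau0")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("ksv", "QuenchFit", function(x) x@ksv)
#' @rdname accessors
#' @export
setMethod("kq", "QuenchFit", function(x) x@kq)
#' @rdname accessors
#' @export
setMethod("temperature", "QuenchFit", function(x) x@temperature)

setMethod("show", "QuenchFit", function(object) {
  cat(sprintf(
    "Stern-Volmer fit @ %g K: Ksv = %.4g L/mol (SD %.2g), Kq = %.4g L/mol/s, R = %.4f\n",
    object@temperature, object@ksv, object@sd, object@kq, object@r))
})

#' BindingFit: a double-logarithm binding fit
#'
#' Result of the regression lg((F0-F)/F) = lg Ka + n lg [Q]: apparent
#' binding constant `ka` and number of binding sites `n`.
#'
#' @slot ka apparent binding constant (L/mol)
#' @slot n number of binding sites (dimensionless)
#' @slot r Pearson correlation on the log-log scale
#' @slot kaSD standard deviation of Ka propagated from the intercept SE
#' @slot temperature K
#' @slot label free text (e.g. site-marker name)
#' @slot nPoints points used
#' @slot nDropped points dropped because F >= F0
#' @export
setClass("BindingFit",
  representation(ka = "numeric", n = "numeric", r = "numeric",
                 kaSD = "numeric", temperature = "numeric",
                 label = "character", nPoints = "integer",
                 nDropped = "integer"))

setValidity("BindingFit", function(object) {
  msg <- character()
  if (object@ka <= 0) msg <- c(msg, "ka must be > 0")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("bindingConstant", "BindingFit", function(x) x@ka)
#' @rdname accessors
#' @export
setMethod("bindingSites", "BindingFit", function(x) x@n)
#' @rdname accessors
#' @export
setMethod("temperature", "BindingFit", function(x) x@temperature)

setMethod("show", "BindingFit", function(object) {
  cat(sprintf(
    "Double-log binding fit @ %g K%s: Ka = %.4g L/mol (SD %.2g), n = %.3f, R = %.4f\n",
    object@temperature,
    if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
    object@ka, object@kaSD, object@n, object@r))
})

#' ThermoResult: Van't Hoff thermodynamics
#'
#' Enthalpy and entropy of binding from ln Ka vs 1/T, per-temperature
#' Gibbs energies by both routes (dH - T dS and -RT ln Ka), and the
#' sign-rule force classification.
#'
#' @slot dH kJ/mol
#' @slot dS J/mol/K
#' @slot dHse,dSse standard errors (same units)
#' @slot temperatures K
#' @slot gibbs kJ/mol by the dH - T dS route (one per temperature)
#' @slot gibbsFromKa kJ/mol by the -RT ln Ka route
#' @slot rCorr correlation coefficient of the Van't Hoff regression
#' @slot forceLabel dominant-force classification
#' @export
setClass("ThermoResult",
  representation(dH = "numeric", dS = "numeric", dHse = "numeric",
                 dSse = "numeric", temperatures = "numeric",
                 gibbs = "numeric", gibbsFromKa = "numeric",
                 rCorr = "numeric", forceLabel = "character"))

setValidity("ThermoResult", function(object) {
  ok <- all(abs(object@gibbs -
                (object@dH - object@temperatures * object@dS / 1000)) <
            1e-9 * pmax(1, abs(object@gibbs)))
  if (!ok) "gibbs must equal dH - T * dS (unit-consistent)" else TRUE
})

#' @rdname accessors
#' @export
setMethod("deltaH", "ThermoResult", function(x) x@dH)
#' @rdname accessors
#' @export
setMethod("deltaS", "ThermoResult", function(x) x@dS)
#' @rdname accessors
#' @export
setMethod("deltaG", "ThermoResult",
          function(x) stats::setNames(x@gibbs, x@temperatures))
#' @rdname accessors
#' @export
setMethod("forceLabel", "ThermoResult", function(x) x@forceLabel)

setMethod("show", "ThermoResult", function(object) {
  cat(sprintf("Van't Hoff: dH = %.2f kJ/mol, dS = %.2f J/mol/K (R = %.4f)\n",
              object@dH, object@dS, object@rCorr))
  for (i in seq_along(object@temperatures))
    cat(sprintf("  T = %g K: dG = %.2f kJ/mol (dH-TdS) | %.2f kJ/mol (-RT lnKa)\n",
                object@temperatures[i], object@gibbs[i],
                object@gibbsFromKa[i]))
  cat("  dominant forces:", object@forceLabel, "\n")
})

#' FretResult: the Forster energy-transfer chain
#'
#' @slot efficiency transfer efficiency E in [0, 1)
#' @slot j overlap integral (units per `jUnits`)
#' @slot jUnits unit tag of `j`
#' @slot r0 critical (50%-efficiency) distance, nm
#' @slot distance donor-acceptor distance r, nm
#' @slot validDistance r < 7 nm
#' @slot validRatio 0.5 R0 < r < 1.5 R0
#' @slot convention `"standard"` or `"paper"` coefficient convention
#' @export
setClass("FretResult",
  representation(efficiency = "numeric", j = "numeric", jUnits = "character",
                 r0 = "numeric", distance = "numeric",
                 validDistance = "logical", validRatio = "logical",
                 convention = "character"))

setValidity("FretResult", function(object) {
  E <- object@efficiency; R0 <- object@r0; r <- object@distance
  if (is.finite(R0) && is.finite(r) && R0 > 0 && r > 0) {
    Echk <- R0^6 / (R0^6 + r^6)
    if (abs(Echk - E) > 1e-9 * max(1e-12, abs(E)))
      return("efficiency, r0 and distance are inconsistent with E = R0^6/(R0^6+r^6)")
  }
  TRUE
})

setMethod("show", "FretResult", function(object) {
  cat(sprintf(
    "FRET (%s convention): E = %.4f, J = %.4g %s, R0 = %.4f nm, r = %.4f nm\n",
    object@convention, object@efficiency, object@j, object@jUnits,
    object@r0, object@distance))
  cat(sprintf("  r < 7 nm: %s | 0.5 R0 < r < 1.5 R0: %s\n",
              object@validDistance, object@validRatio))
})

#' SecondaryStructure: protein secondary-structure composition
#'
#' @slot fractions named percentages (alpha-helix, beta-sheet, beta-turn,
#'   beta-antiparallel, random coil as applicable)
#' @slot method `"CD"` or `"FTIR"`
#' @export
setClass("SecondaryStructure",
  representation(fractions = "numeric", method = "character"))

setValidity("SecondaryStructure", function(object) {
  msg <- character()
  if (any(object@fractions < -1e-9) || any(object@fractions > 100 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 100]")
  if (object@method == "FTIR" &&
      abs(sum(object@fractions) - 100) > 0.5)
    msg <- c(msg, "FTIR fractions must sum to 100 +/- 0.5")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("structureFractions", "SecondaryStructure", function(x) x@fractions)

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("Secondary structure (%s):\n", object@method))
  for (nm in names(object@fractions))
    cat(sprintf("  %-16s %6.2f %%\n", nm, object@fractions[nm]))
})

#' Ic50Result: half-maximal scavenging concentration
#'
#' @slot ic50 ug/mL
#' @slot params fitted curve parameters (named)
#' @slot residual residual sum of squares of the fit (NA for interpolation)
#' @slot method `"loglogistic"` or `"interp"`
#' @slot extrapolated TRUE when the IC50 lies outside the measured span
#'   or the data never cross 50%
#' @slot span measured concentration range (ug/mL)
#' @export
setClass("Ic50Result",
  representation(ic50 = "numeric", params = "numeric", residual = "numeric",
                 method = "character", extrapolated = "logical",
                 span = "numeric"))

#' @rdname accessors
#' @export
setMethod("ic50", "Ic50Result", function(x) x@ic50)

setMethod("show", "Ic50Result", function(object) {
  cat(sprintf("IC50 = %.4g ug/mL (%s%s)\n", object@ic50, object@method,
              if (object@extrapolated) ", extrapolated" else ""))
})

# as.list methods: expose every slot of result objects as a plain list
.slots_as_list <- function(x)
  stats::setNames(lapply(methods::slotNames(x), methods::slot, object = x),
                  methods::slotNames(x))

#' @rdname accessors
#' @export
setMethod("as.list", "QuenchFit", function(x, ...) .slots_as_list(x))
#' @rdname accessors
#' @export
setMethod("as.list", "BindingFit", function(x, ...) .slots_as_list(x))
#' @rdname accessors
#' @export
setMethod("as.list", "ThermoResult", function(x, ...) .slots_as_list(x))
#' @rdname accessors
#' @export
setMethod("as.list", "FretResult", function(x, ...) .slots_as_list(x))
#' @rdname accessors
#' @export
setMethod("as.list", "SecondaryStructure", function(x, ...) .slots_as_list(x))
#' @rdname accessors
#' @export
setMethod("as.list", "Ic50Result", function(x, ...) .slots_as_list(x))
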