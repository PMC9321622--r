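#' @include AllClasses.R utils.R spectra.R
NULL

#' FRET configuration
#'
#' Photophysical constants for the Forster chain. The defaults are the
#' values conventionally adopted for serum-albumin donors: orientation
#' factor k2 = 2/3 (isotropic dynamic averaging), refractive index
#' 1.336 (aqueous buffer), donor quantum yield 0.118 (Trp in albumin).
#' All three are defaults, not constants: supply measured values when
#' available.
#'
#' Two coefficient conventions are supported because the literature
#' mixes unit systems for the critical-distance relation
#' R0^6 = C k2 n^-4 Phi J:
#' `"standard"` uses C = 8.79e-5 with J in nm^4 M^-1 cm^-1 and R0 in
#' Angstrom (returned in nm); `"paper"` applies C = 8.78e-23 literally
#' with J in cm^3 L mol^-1 and tags the result as-printed. The two are
#' not mutually consistent on published value triplets, which is why
#' the (E, R0) -> r inversion - not the J -> R0 step - is the canonical
#' route to the donor-acceptor distance.
#'
#' @param k2 orientation factor, in (0, 4]
#' @param nRefr refractive index of the medium
#' @param phi donor quantum yield
#' @param convention `"standard"` or `"paper"`
#' @return a list of class `"FretConfig"`
#' @export
fretConfig <- function(k2 = 2 / 3, nRefr = 1.336, phi = 0.118,
                       convention = c("standard", "paper")) {
  convention <- match.arg(convention)
  stopifnot(k2 > 0, k2 <= 4, nRefr > 0, phi > 0)
  structure(list(k2 = k2, nRefr = nRefr, phi = phi,
                 convention = convention,
                 r0Coefficient = if (convention == "standard") 8.79e-5
                                 else 8.78e-23),
            class = "FretConfig")
}

#' Energy-transfer efficiency from intensities
#'
#' E = 1 - F/F0 for equimolar donor with and without acceptor.
#'
#' @param f fluorescence intensity with acceptor (0 < f <= f0)
#' @param f0 fluorescence intensity without acceptor (> 0)
#' @return efficiency in [0, 1)
#' @examples
#' transferEfficiency(0.8426, 1)  # 0.1574
#' @export
transferEfficiency <- function(f, f0) {
  stopifnot(f0 > 0, f > 0)
  if (f > f0) stop("F > F0 would give negative efficiency")
  1 - f / f0
}

#' Spectral overlap integral
#'
#' J = sum F(l) eps(l) l^4 dl / sum F(l) dl over the wavelength range
#' where the donor emission and the acceptor molar absorptivity
#' overlap, evaluated with trapezoid weights after linearly
#' interpolating the acceptor spectrum onto the donor grid restricted
#' to the common range. The donor spectrum need not be normalized - the
#' denominator cancels any scale. With `lambdaUnit = "nm"` (standard) J
#' carries nm^4 M^-1 cm^-1; with `"cm"` the wavelengths are converted
#' to cm first and J carries cm^3 L mol^-1 (cm^4 M^-1 cm^-1).
#'
#' @param donorEmission [Spectrum-class] of kind `"emission"`
#' @param acceptorEpsilon [Spectrum-class] of kind
#'   `"molar_absorptivity"` (M^-1 cm^-1)
#' @param lambdaUnit `"nm"` or `"cm"`
#' @return named list: `j`, `units`, `range` (common wavelength range, nm)
#' @export
overlapIntegral <- function(donorEmission, acceptorEpsilon,
                            lambdaUnit = c("nm", "cm")) {
  lambdaUnit <- match.arg(lambdaUnit)
  stopifnot(is(donorEmission, "Spectrum"), is(acceptorEpsilon, "Spectrum"))
  lo <- max(min(donorEmission@axis), min(acceptorEpsilon@axis))
  hi <- min(max(donorEmission@axis), max(acceptorEpsilon@axis))
  if (lo >= hi) stop("donor and acceptor wavelength ranges do not overlap")
  keep <- donorEmission@axis >= lo & donorEmission@axis <= hi
  lam <- donorEmission@axis[keep]
  if (length(lam) < 2) stop("fewer than 2 grid points in the common range")
  fl <- donorEmission@signal[keep]
  eps <- stats::approx(acceptorEpsilon@axis, acceptorEpsilon@signal,
                       xout = lam)$y
  lamU <- if (lambdaUnit == "cm") lam * 1e-7 else lam
  w <- .trapWeights(lamU)
  den <- sum(fl * w)
  if (den <= 0) stop("donor emission integrates to a non-positive value")
  j <- sum(fl * eps * lamU^4 * w) / den
  list(j = j,
       units = if (lambdaUnit == "nm") "nm4.M-1.cm-1" else "cm3.L.mol-1",
       range = c(lo, hi))
}

#' Forster critical distance from the overlap integral
#'
#' Standard convention: R0(A)^6 = 8.79e-5 k2 n^-4 Phi J with J in
#' nm^4 M^-1 cm^-1; the result is returned in nm. Paper convention:
#' R0^6 = 8.78e-23 k2 n^-4 Phi J applied literally to J in
#' cm^3 L mol^-1, returned as the sixth root without unit rescaling
#' (tagged as-printed); interpret with care, see [fretConfig()].
#'
#' @param j overlap integral, >= 0, in the convention's units
#' @param config a [fretConfig()] list
#' @return R0; nm under the standard convention
#' @export
forsterRadius <- function(j, config = fretConfig()) {
  stopifnot(inherits(config, "FretConfig"))
  if (j < 0) stop("negative overlap integral")
  base <- config$r0Coefficient * config$k2 * config$nRefr^-4 *
    config$phi * j
  r0 <- base^(1 / 6)
  if (config$convention == "standard") r0 / 10 else r0  # Angstrom -> nm
}

#' Donor-acceptor distance from efficiency and critical distance
#'
#' Inverts E = R0^6 / (R0^6 + r^6): r = R0 ((1 - E)/E)^(1/6).
#'
#' @param e efficiency, strictly inside (0, 1)
#' @param r0 critical distance (nm), > 0
#' @return r in nm
#' @examples
#' donorAcceptorDistance(0.1574, 2.3749)  # 3.1411 nm
#' @export
donorAcceptorDistance <- function(e, r0) {
  stopifnot(r0 > 0)
  if (e <= 0 || e >= 1) stop("efficiency must lie strictly in (0, 1)")
  r0 * ((1 - e) / e)^(1 / 6)
}

#' FRET validity flags
#'
#' The Forster analysis is considered physically meaningful when the
#' donor-acceptor distance is below 7 nm and lies strictly within
#' (0.5 R0, 1.5 R0).
#'
#' @param r donor-acceptor distance (nm), > 0
#' @param r0 critical distance (nm), > 0
#' @return named logical `c(valid_distance, valid_ratio)`
#' @export
fretValidity <- function(r, r0) {
  stopifnot(r > 0, r0 > 0)
  c(valid_distance = r < 7,
    valid_ratio = r > 0.5 * r0 && r < 1.5 * r0)
}

#' Full Forster chain from spectra and intensities
#'
#' Convenience wrapper running efficiency, overlap integral, critical
#' distance, distance and validity in one call and returning a
#' [FretResult-class]. The stored (E, R0, r) triplet is consistent by
#' construction: r is obtained by inverting the efficiency relation at
#' the computed R0.
#'
#' @param f,f0 donor intensity with / without acceptor
#' @param donorEmission,acceptorEpsilon spectra, see [overlapIntegral()]
#' @param config a [fretConfig()]
#' @return a [FretResult-class]
#' @export
fretAnalysis <- function(f, f0, donorEmission, acceptorEpsilon,
                         config = fretConfig()) {
  e <- transferEfficiency(f, f0)
  ov <- overlapIntegral(donorEmission, acceptorEpsilon,
                        lambdaUnit = if (config$convention == "standard")
                          "nm" else "cm")
  r0 <- forsterRadius(ov$j, config)
  r <- donorAcceptorDistance(e, r0)
  v <- fretValidity(r, r0)
  new("FretResult", efficiency = e, j = ov$j, jUnits = ov$units,
      r0 = r0, distance = r,
      validDistance = unname(v["valid_distance"]),
      validRatio = unname(v["valid_ratio"]),
      convention = config$convention)
}
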