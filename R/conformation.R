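#' @include AllClasses.R utils.R spectra.R
NULL

#' Synchronous-fluorescence quench profile
#'
#' Synchronous scans at a fixed excitation-emission offset report the
#' microenvironment of specific residue classes: delta-lambda = 15 nm
#' follows tyrosine, 60 nm tryptophan. Given one spectrum per quencher
#' concentration, this extracts each peak (position, intensity),
#' regresses F0/F on \[Q\] (ordinary least squares; the
#' zero-concentration point is excluded as definitionally exact) and
#' reports the net peak shift (last minus first concentration).
#'
#' @param spectra list of [Spectrum-class], one per concentration,
#'   sharing a common axis range
#' @param concentrations quencher concentrations (mol/L), ascending,
#'   first entry typically 0 (the F0 reference)
#' @param deltaLambda offset in nm, conventionally 15 or 60
#' @param window optional axis window for the peak search
#' @return list: `delta_lambda`, `peaks` (data.frame of concentration,
#'   position, intensity), `slope` (L/mol, the synchronous quenching
#'   constant), `shift` (nm), `r` (correlation of the regression)
#' @export
synchronousProfile <- function(spectra, concentrations,
                               deltaLambda = 60, window = NULL) {
  stopifnot(is.list(spectra), length(spectra) >= 3,
            length(spectra) == length(concentrations),
            all(vapply(spectra, is, logical(1), "Spectrum")),
            all(diff(concentrations) > 0))
  lo <- max(vapply(spectra, function(s) min(s@axis), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s@axis), numeric(1)))
  if (lo >= hi) stop("spectra do not share a common axis range")
  if (is.null(window)) window <- c(lo, hi)
  pk <- t(vapply(spectra, peakOf, numeric(2), window = window))
  peaks <- data.frame(concentration = concentrations,
                      position = pk[, "position"],
                      intensity = pk[, "intensity"])
  f0 <- peaks$intensity[1]
  use <- concentrations > 0
  if (sum(use) < 2)
    stop("need >= 2 nonzero concentrations for the quench slope")
  ols <- .ols(concentrations[use], f0 / peaks$intensity[use])
  list(delta_lambda = deltaLambda, peaks = peaks,
       slope = ols$slope,
       shift = peaks$position[nrow(peaks)] - peaks$position[1],
       r = ols$r)
}

#' Mean residue ellipticity
#'
#' MRE = theta_obs / (10 cp n l): the observed ellipticity in
#' millidegrees normalized per residue, per molar concentration and per
#' cm of path length, in deg cm^2 dmol^-1.
#'
#' @param thetaObs observed ellipticity, mdeg
#' @param cp molar protein concentration, mol/L (> 0)
#' @param nRes residue count (585 for human serum albumin)
#' @param pathLength cuvette path length, cm (default 0.1, a 1 mm cell)
#' @return MRE in deg cm^2 dmol^-1
#' @export
meanResidueEllipticity <- function(thetaObs, cp, nRes = 585,
                                   pathLength = 0.1) {
  stopifnot(cp > 0, pathLength > 0, nRes >= 1)
  den <- 10 * cp * nRes * pathLength
  if (den == 0) stop("zero denominator in MRE")
  thetaObs / den
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' Two-anchor formula: helix % = 100 (-MRE208 - 4000) / (33000 - 4000),
#' where -4000 is the 208 nm MRE of beta/random-coil structure and
#' -33000 that of pure alpha-helix. Values outside [0, 100] are clamped
#' with a warning (they indicate MRE outside the anchor range).
#'
#' @param mre208 mean residue ellipticity at 208 nm, deg cm^2 dmol^-1
#' @return percent alpha-helix in [0, 100]
#' @examples
#' alphaHelixFraction(-21180)  # about 59.24
#' @export
alphaHelixFraction <- function(mre208) {
  stopifnot(is.finite(mre208))
  pct <- 100 * (-mre208 - 4000) / (33000 - 4000)
  if (pct < 0 || pct > 100) {
    warning("MRE208 outside the [-33000, -4000] anchor range; clamped")
    pct <- min(100, max(0, pct))
  }
  pct
}

#' Alpha-helix content from a CD trace
#'
#' Convenience chain: read theta at 208 nm off an ellipticity spectrum
#' (nearest grid point), convert to MRE, apply the two-anchor helix
#' formula, and return a [SecondaryStructure-class] tagged `"CD"`.
#'
#' @param cdSpectrum [Spectrum-class] of kind `"ellipticity"` (nm, mdeg)
#' @param cp,nRes,pathLength see [meanResidueEllipticity()]
#' @return a [SecondaryStructure-class] with a single `alpha_helix` entry
#' @export
cdHelixContent <- function(cdSpectrum, cp, nRes = 585, pathLength = 0.1) {
  stopifnot(is(cdSpectrum, "Spectrum"),
            cdSpectrum@kind == "ellipticity")
  i <- which.min(abs(cdSpectrum@axis - 208))
  theta <- cdSpectrum@signal[i]
  mre <- meanResidueEllipticity(theta, cp, nRes, pathLength)
  new("SecondaryStructure",
      fractions = c(alpha_helix = alphaHelixFraction(mre)),
      method = "CD")
}

#' Default amide-I band configuration
#'
#' Component windows and initial centers following common amide-I
#' assignments: beta-sheet 1610-1640, random coil 1640-1648, alpha-helix
#' 1648-1660, beta-turn 1660-1680, beta-antiparallel 1680-1695 cm^-1.
#' Windows are configuration rather than constants; edit the returned
#' data.frame to match other assignment schemes.
#'
#' @return data.frame with columns `component`, `center`, `lower`, `upper`
#' @export
amideBandConfig <- function() {
  data.frame(
    component = c("beta_sheet", "random_coil", "alpha_helix",
                  "beta_turn", "beta_antiparallel"),
    center = c(1627, 1644, 1654, 1670, 1688),
    lower = c(1610, 1640, 1648, 1660, 1680),
    upper = c(1640, 1648, 1660, 1680, 1695),
    stringsAsFactors = FALSE)
}

#' Amide-I band decomposition of an FTIR spectrum
#'
#' Least-squares decomposition of the amide-I envelope
#' (1600-1700 cm^-1) into Gaussian component bands over a linear
#' baseline co-estimated with the bands. Secondary-structure
#' fractions are the component areas normalized to 100 %, with each
#' band assigned to the structure class of its window. Centers are
#' bounded within their configured windows during the fit.
#'
#' Initialization is two-stage: amplitudes are first solved linearly at
#' the configured centers and a common starting width, then all
#' parameters are refined by bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]).
#'
#' @param ftirSpectrum [Spectrum-class] of kind `"ftir"` covering
#'   1600-1700 cm^-1
#' @param bandConfig data.frame as returned by [amideBandConfig()];
#'   fewer than five bands is allowed and labels follow the config
#' @param region amide-I region bounds, cm^-1
#' @param startWidth initial Gaussian sigma, cm^-1
#' @return a [SecondaryStructure-class] tagged `"FTIR"`; the fitted
#'   band table is attached as attribute `"bands"` and the residual
#'   norm as attribute `"rss"`
#' @export
amideBandFit <- function(ftirSpectrum, bandConfig = amideBandConfig(),
                         region = c(1600, 1700), startWidth = 6) {
  stopifnot(is(ftirSpectrum, "Spectrum"), ftirSpectrum@kind == "ftir",
            nrow(bandConfig) >= 1)
  if (min(ftirSpectrum@axis) > region[1] ||
      max(ftirSpectrum@axis) < region[2])
    stop("spectrum must cover the amide-I region ",
         region[1], "-", region[2], " cm^-1")
  keep <- ftirSpectrum@axis >= region[1] & ftirSpectrum@axis <= region[2]
  x <- ftirSpectrum@axis[keep]
  y <- ftirSpectrum@signal[keep]
  # linear baseline: estimated from the region edges for initialization,
  # then refined as part of the least-squares model so band tails at the
  # edges are not mistaken for baseline
  n <- length(x)
  m <- max(1L, min(5L, n %/% 10L))
  i1 <- seq_len(m); i2 <- seq(n - m + 1L, n)
  b1start <- (mean(y[i2]) - mean(y[i1])) / (mean(x[i2]) - mean(x[i1]))
  b0start <- mean(y[i1]) - b1start * mean(x[i1])
  k <- nrow(bandConfig)
  centers <- bandConfig$center
  # stage 1: linear amplitude solve at fixed centers/widths
  B <- cbind(sapply(seq_len(k), function(i)
    exp(-(x - centers[i])^2 / (2 * startWidth^2))), 1, x)
  sol <- qr.solve(B, y)
  a0 <- pmax(sol[seq_len(k)], max(abs(y)) * 1e-6)
  # stage 2: bounded Levenberg-Marquardt refinement
  terms <- sprintf("a%d * exp(-(x - c%d)^2 / (2 * w%d^2))",
                   seq_len(k), seq_len(k), seq_len(k))
  fml <- stats::as.formula(paste("y ~ b0 + b1 * (x - ", region[1], ") +",
                                 paste(terms, collapse = " + ")))
  start <- c(stats::setNames(as.list(a0), paste0("a", seq_len(k))),
             stats::setNames(as.list(centers), paste0("c", seq_len(k))),
             stats::setNames(as.list(rep(startWidth, k)),
                             paste0("w", seq_len(k))),
             list(b0 = b0start + b1start * region[1], b1 = b1start))
  lower <- c(rep(0, k), bandConfig$lower, rep(2, k), -Inf, -Inf)
  upper <- c(rep(Inf, k), bandConfig$upper, rep(15, k), Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = list(x = x, y = y), start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-14, ptol = 1e-14)),
    error = function(e)
      stop("amide-I band fit did not converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  a <- cf[paste0("a", seq_len(k))]
  cc <- cf[paste0("c", seq_len(k))]
  w <- cf[paste0("w", seq_len(k))]
  areas <- a * w * sqrt(2 * pi)
  if (sum(areas) <= 0) stop("degenerate fit: zero total band area")
  fractions <- 100 * areas / sum(areas)
  out <- new("SecondaryStructure",
             fractions = stats::setNames(as.numeric(fractions),
                                         bandConfig$component),
             method = "FTIR")
  attr(out, "bands") <- data.frame(component = bandConfig$component,
                                   amplitude = as.numeric(a),
                                   center = as.numeric(cc),
                                   sigma = as.numeric(w),
                                   area = as.numeric(areas))
  attr(out, "rss") <- sum(stats::residuals(fit)^2)
  out
}
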