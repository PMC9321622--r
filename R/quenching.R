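#' @include AllClasses.R utils.R
NULL

#' Stern-Volmer analysis of a fluorescence titration
#'
#' Fits F0/F = 1 + Ksv \[Q\] by ordinary least squares with a free
#' intercept. The zero-concentration point (F0/F = 1 by definition) is
#' excluded from the regression so it cannot over-weight the origin; the
#' fitted intercept is kept as a diagnostic of how far the data depart
#' from the ideal 1. The bimolecular quenching rate constant is
#' Kq = Ksv / tau0; for serum albumin the unquenched lifetime tau0 is
#' conventionally 1e-8 s, so Ksv values of ~1e4 L/mol map to Kq ~1e12
#' L/mol/s, far above the diffusion limit - the signature of static
#' (ground-state complex) quenching.
#'
#' @param series a [TitrationSeries-class]
#' @param tau0 unquenched fluorophore lifetime in seconds (default 1e-8)
#' @return a [QuenchFit-class]
#' @examples
#' q <- seq(2.5e-6, 2.5e-5, 2.5e-6)
#' f0 <- 1000; f <- f0 / (1 + 5.7e4 * q)
#' ksv(sternVolmerFit(TitrationSeries(q, f, F0 = f0)))  # 5.7e4
#' @export
sternVolmerFit <- function(series, tau0 = 1e-8) {
  stopifnot(is(series, "TitrationSeries"), tau0 > 0)
  use <- series@concentration > 0
  q <- series@concentration[use]
  ratio <- series@F0 / series@intensity[use]
  if (length(q) < 3)
    stop("Stern-Volmer fit needs >= 3 nonzero-concentration points")
  ols <- .ols(q, ratio)
  new("QuenchFit", ksv = ols$slope, kq = ols$slope / tau0, tau0 = tau0,
      intercept = ols$intercept, r = ols$r, sd = ols$slope_se,
      temperature = series@temperature, nPoints = length(q))
}

#' Inner-filter-effect correction of titration intensities
#'
#' Optional pre-step: F_corr = F * 10^((A_ex + A_em) / 2), where A_ex
#' and A_em are the solution absorbances at the excitation and emission
#' wavelengths for each titration point. Off by default throughout the
#' package; apply it explicitly when absorbances are available.
#'
#' @param series a [TitrationSeries-class]
#' @param aEx,aEm absorbance at the excitation / emission wavelength,
#'   either scalars or one value per titration point
#' @param aEx0,aEm0 absorbances for the zero-quencher reference used to
#'   correct F0 (default 0: F0 uncorrected)
#' @return a corrected [TitrationSeries-class]
#' @export
innerFilterCorrect <- function(series, aEx, aEm, aEx0 = 0, aEm0 = 0) {
  stopifnot(is(series, "TitrationSeries"))
  corr <- series@intensity * 10^((aEx + aEm) / 2)
  f0 <- series@F0 * 10^((aEx0 + aEm0) / 2)
  new("TitrationSeries", concentration = series@concentration,
      intensity = corr, F0 = f0, temperature = series@temperature,
      readOut = series@readOut)
}

#' Classify the quenching mechanism across temperatures
#'
#' Joint rule: "static" requires Ksv non-increasing with temperature AND
#' every Kq above the diffusion-limited collisional maximum (2e10
#' L/mol/s by default); "dynamic" requires the opposite on both counts
#' (Ksv non-decreasing, all Kq at or below the threshold). Any
#' disagreement between the two criteria yields "indeterminate", with
#' both pieces of evidence reported.
#'
#' @param fits list of [QuenchFit-class] at >= 2 distinct temperatures
#' @param kqThreshold diffusion-limit threshold, L/mol/s
#' @return a list with elements `mechanism` (`"static"`, `"dynamic"` or
#'   `"indeterminate"`), `ksv_trend`, `kq_above_threshold`,
#'   `temperatures`, `ksv`, `kq`, `kq_threshold`
#' @export
classifyQuenching <- function(fits, kqThreshold = 2e10) {
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, is, logical(1), "QuenchFit")))
  temps <- vapply(fits, temperature, numeric(1))
  if (anyDuplicated(temps))
    stop("duplicate temperatures in quench fits")
  ord <- order(temps)
  temps <- temps[ord]
  ksvs <- vapply(fits, ksv, numeric(1))[ord]
  kqs <- vapply(fits, kq, numeric(1))[ord]
  nonIncreasing <- all(diff(ksvs) <= 0)
  nonDecreasing <- all(diff(ksvs) >= 0)
  allAbove <- all(kqs > kqThreshold)
  allBelow <- all(kqs <= kqThreshold)
  mech <- if (nonIncreasing && allAbove) "static"
          else if (nonDecreasing && allBelow) "dynamic"
          else "indeterminate"
  list(mechanism = mech,
       ksv_trend = if (nonIncreasing && nonDecreasing) "constant"
                   else if (nonIncreasing) "decreasing"
                   else if (nonDecreasing) "increasing" else "non-monotone",
       kq_above_threshold = allAbove,
       temperatures = temps, ksv = ksvs, kq = kqs,
       kq_threshold = kqThreshold)
}

#' Read a long-format titration table
#'
#' Columns: `temperature_K`, `quencher_mol_per_L`, `intensity`, and
#' optionally `label` (e.g. a site-marker name). One
#' [TitrationSeries-class] is built per (label, temperature); F0 is
#' taken from the zero-concentration row of each series.
#'
#' @param path delimited text file
#' @param sep column delimiter
#' @return named list of [TitrationSeries-class]; names are
#'   `"<label>@<T>K"` (or `"<T>K"` without labels)
#' @export
readTitrationTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("temperature_K", "quencher_mol_per_L", "intensity")
  if (!all(need %in% names(df)))
    stop("titration table must have columns: ",
         paste(need, collapse = ", "))
  if (!"label" %in% names(df)) df$label <- ""
  out <- list()
  for (lab in unique(df$label)) for (tt in unique(df$temperature_K[df$label == lab])) {
    sub <- df[df$label == lab & df$temperature_K == tt, ]
    sub <- sub[order(sub$quencher_mol_per_L), ]
    nm <- if (nzchar(lab)) sprintf("%s@%gK", lab, tt) else sprintf("%gK", tt)
    out[[nm]] <- TitrationSeries(sub$quencher_mol_per_L, sub$intensity,
                                 temperature = tt)
  }
  out
}

#' Write titration series to a long-format table
#'
#' @param seriesList named list of [TitrationSeries-class]
#' @param path output file
#' @param labels optional character vector of labels (recycled)
#' @return `path`, invisibly
#' @export
writeTitrationTable <- function(seriesList, path, labels = NULL) {
  if (is(seriesList, "TitrationSeries")) seriesList <- list(seriesList)
  rows <- lapply(seq_along(seriesList), function(i) {
    s <- seriesList[[i]]
    data.frame(label = if (is.null(labels)) "" else labels[[i]],
               temperature_K = s@temperature,
               quencher_mol_per_L = s@concentration,
               intensity = s@intensity)
  })
  df <- do.call(rbind, rows)
  if (all(!nzchar(df$label))) df$label <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
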