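#' @include AllClasses.R utils.R
NULL

#' Read a two-column spectrum from delimited text
#'
#' Reads a wavelength/signal (or wavenumber/absorbance) trace from a
#' delimited text file. A single non-numeric header line is tolerated;
#' any other non-numeric row raises an error naming the offending line.
#' Decreasing axes (typical FTIR export order) are reversed so the
#' stored axis is strictly increasing, and the reversal is noted in the
#' spectrum label.
#'
#' @param path file path
#' @param kind spectral kind, see [Spectrum-class]
#' @param sep column delimiter; `""` means any whitespace
#' @param comment comment-line prefix
#' @param label provenance label (defaults to the file name)
#' @return a [Spectrum-class]
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, kind = "emission", sep = ",",
                         comment = "#", label = basename(path)) {
  m <- .readTwoColumns(path, sep = sep, comment = comment)
  if (nrow(m) < 2) stop("a spectrum needs at least 2 points: ", path)
  Spectrum(m[, 1], m[, 2], kind = kind, label = label)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spectrum a [Spectrum-class]
#' @param path output file
#' @param sep column delimiter
#' @return `path`, invisibly
#' @export
writeSpectrum <- function(spectrum, path, sep = ",") {
  stopifnot(is(spectrum, "Spectrum"))
  lines <- paste(format(spectrum@axis, digits = 17, trim = TRUE),
                 format(spectrum@signal, digits = 17, trim = TRUE),
                 sep = sep)
  writeLines(lines, path)
  invisible(path)
}

# restrict a spectrum to a window, erroring usefully
.windowIdx <- function(spectrum, window) {
  if (is.null(window)) return(seq_along(spectrum@axis))
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- which(spectrum@axis >= window[1] & spectrum@axis <= window[2])
  if (!length(idx))
    stop("window [", window[1], ", ", window[2],
         "] contains no axis points")
  idx
}

#' Locate the peak of a spectrum
#'
#' Grid-based peak localization: the axis position and value of the
#' maximum signal inside `window` (or the full axis). No sub-grid
#' interpolation is done, matching how instrument software reports peak
#' positions; ties are broken toward the smaller axis value.
#'
#' @param spectrum a [Spectrum-class]
#' @param window `c(lo, hi)` axis interval, or `NULL` for the whole axis
#' @return named numeric `c(position, intensity)`
#' @examples
#' s <- Spectrum(220:500, 1000 * exp(-((220:500) - 327)^2 / (2 * 25^2)),
#'               kind = "emission")
#' peakOf(s)  # 327 nm
#' @export
peakOf <- function(spectrum, window = NULL) {
  stopifnot(is(spectrum, "Spectrum"))
  idx <- .windowIdx(spectrum, window)
  j <- idx[which.max(spectrum@signal[idx])]  # which.max: first max = smallest axis
  c(position = spectrum@axis[j], intensity = spectrum@signal[j])
}

#' Peak shift and intensity change between two spectra
#'
#' Compares a perturbed spectrum (e.g. protein + ligand) against a
#' reference: peak displacement (positive = red shift) and percent
#' intensity change with the convention that a positive percentage means
#' a decrease, as quench percentages are usually quoted.
#'
#' @param reference,perturbed [Spectrum-class] objects of the same kind
#' @param window optional axis window passed to [peakOf()]
#' @return named numeric `c(shift, percent_decrease)`
#' @examples
#' # Native peak (330 nm, 1539 a.u.) vs complex peak (320 nm, 1291 a.u.)
#' # gives shift -10 nm and a 16.11 % intensity decrease.
#' @export
shiftMetrics <- function(reference, perturbed, window = NULL) {
  stopifnot(is(reference, "Spectrum"), is(perturbed, "Spectrum"))
  if (reference@kind != perturbed@kind)
    stop("spectra must share kind (", reference@kind, " vs ",
         perturbed@kind, ")")
  pr <- peakOf(reference, window)
  pp <- peakOf(perturbed, window)
  if (pr["intensity"] == 0)
    stop("reference peak intensity is 0; percent change undefined")
  c(shift = unname(pp["position"] - pr["position"]),
    percent_decrease = unname(
      100 * (pr["intensity"] - pp["intensity"]) / pr["intensity"]))
}

#' Read / write an excitation-emission matrix CSV
#'
#' The format is a matrix CSV whose first row holds the emission axis
#' (first cell empty or a label) and whose first column holds the
#' excitation axis.
#'
#' @param path file path
#' @return an [EEMatrix-class]
#' @export
readEEM <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, check.names = FALSE)
  em <- suppressWarnings(as.numeric(raw[1, -1]))
  ex <- suppressWarnings(as.numeric(raw[-1, 1]))
  if (anyNA(em) || anyNA(ex)) stop("non-numeric EEM axes in ", path)
  mat <- as.matrix(raw[-1, -1])
  mode(mat) <- "numeric"
  dimnames(mat) <- NULL
  EEMatrix(ex, em, mat)
}

#' @param eem an [EEMatrix-class]
#' @rdname readEEM
#' @export
writeEEM <- function(eem, path) {
  stopifnot(is(eem, "EEMatrix"))
  header <- paste(c("", format(eem@emission, digits = 17, trim = TRUE)),
                  collapse = ",")
  rows <- vapply(seq_along(eem@excitation), function(i)
    paste(c(format(eem@excitation[i], digits = 17, trim = TRUE),
            format(eem@intensity[i, ], digits = 17, trim = TRUE)),
          collapse = ","), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Find fluorescence peaks in an excitation-emission matrix
#'
#' Local maxima of the EEM intensity surface, excluding first- and
#' second-order Rayleigh scatter ridges (|em - ex| <= halfwidth and
#' |em - 2 ex| <= halfwidth). In serum-albumin landscapes the two
#' physical peaks are the Trp/Tyr transition (ex ~280 nm) and the
#' polypeptide-backbone transition (ex ~230 nm).
#'
#' @param eem an [EEMatrix-class]
#' @param scatterHalfwidth scatter-exclusion half width in nm (>= 0);
#'   default 15 nm, standard EEM practice
#' @param minRelIntensity minimum peak intensity as a fraction of the
#'   matrix maximum; suppresses numerical-tail artifacts
#' @return a data.frame with columns `excitation`, `emission`,
#'   `stokes_shift` (= emission - excitation) and `intensity`, sorted by
#'   decreasing intensity; zero rows when everything is excluded
#' @export
findEEMPeaks <- function(eem, scatterHalfwidth = 15,
                         minRelIntensity = 1e-6) {
  stopifnot(is(eem, "EEMatrix"), scatterHalfwidth >= 0)
  ex <- eem@excitation; em <- eem@emission; z <- eem@intensity
  nr <- nrow(z); nc <- ncol(z)
  floorInt <- minRelIntensity * max(z)
  excl <- outer(ex, em, function(x, m)
    abs(m - x) <= scatterHalfwidth | abs(m - 2 * x) <= scatterHalfwidth)
  hits <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (excl[i, j]) next
    v <- z[i, j]
    if (v <= 0 || v < floorInt) next
    nbr <- expand.grid(di = -1:1, dj = -1:1)
    isMax <- TRUE
    for (k in seq_len(nrow(nbr))) {
      if (nbr$di[k] == 0 && nbr$dj[k] == 0) next
      ii <- i + nbr$di[k]; jj <- j + nbr$dj[k]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (z[ii, jj] > v) { isMax <- FALSE; break }
    }
    if (isMax)
      hits[[length(hits) + 1L]] <-
        data.frame(excitation = ex[i], emission = em[j],
                   stokes_shift = em[j] - ex[i], intensity = v)
  }
  if (!length(hits))
    return(data.frame(excitation = numeric(), emission = numeric(),
                      stokes_shift = numeric(), intensity = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
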