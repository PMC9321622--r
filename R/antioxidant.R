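#' @include AllClasses.R utils.R
NULL

#' DPPH radical-scavenging percentage
#'
#' Default (standard) definition: 100 (A_control - A_sample) /
#' A_control, the fraction of the radical's 521 nm absorbance removed.
#' A `"literal"` mode computes 100 (A_control - A_sample / A_sample)
#' for auditing against reports that print the expression in that
#' (dimensionally inconsistent) form; it is not recommended for
#' analysis.
#'
#' @param aControl absorbance of the radical solution alone (> 0)
#' @param aSample absorbance with antioxidant present (vectorized)
#' @param mode `"standard"` or `"literal"`
#' @return scavenging percent (vector)
#' @examples
#' scavengingPercent(0.8, 0.4)  # 50
#' @export
scavengingPercent <- function(aControl, aSample,
                              mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  stopifnot(aControl > 0, all(aSample >= 0))
  if (mode == "standard")
    return(100 * (aControl - aSample) / aControl)
  if (any(aSample == 0))
    stop("literal mode divides by A_sample; A_sample = 0 not allowed")
  100 * (aControl - aSample / aSample)
}

#' Dose-response IC50 estimation
#'
#' Fits the scavenging-vs-concentration curve and reports the
#' half-maximal concentration. The default `"loglogistic"` method fits
#' the two-parameter log-logistic model
#' percent = 100 / (1 + (IC50 / c)^h) (lower asymptote 0 %, upper
#' 100 %, matching the bounded assay response) by Levenberg-Marquardt;
#' `"interp"` uses monotone linear interpolation between the points
#' bracketing 50 % and requires monotone responses. The result is
#' flagged `extrapolated` when the data never cross 50 % or the IC50
#' falls outside the measured span.
#'
#' @param concentration concentrations, ug/mL, ascending
#' @param percent scavenging percentages (same length)
#' @param method `"loglogistic"` or `"interp"`
#' @return an [Ic50Result-class]
#' @examples
#' fitIC50(c(5, 15), c(40, 60), method = "interp")  # IC50 = 10
#' @export
fitIC50 <- function(concentration, percent,
                    method = c("loglogistic", "interp")) {
  method <- match.arg(method)
  stopifnot(length(concentration) == length(percent),
            all(concentration > 0), all(diff(concentration) > 0))
  span <- range(concentration)
  crosses <- min(percent) < 50 && max(percent) > 50
  if (method == "interp") {
    if (any(diff(percent) < 0))
      stop("non-monotone responses; use method = \"loglogistic\"")
    if (!crosses) {
      # no bracketing pair: extend the first/last segment
      i <- if (max(percent) <= 50) length(percent) - 1 else 1
    } else {
      i <- max(which(percent < 50))
    }
    slope <- (percent[i + 1] - percent[i]) /
             (concentration[i + 1] - concentration[i])
     icc <- concentration[i] + (50 - percent[i]) / slope
    return(new("Ic50Result", ic50 = icc, params = c(slope = slope),
               residual = NA_real_, method = "interp",
               extrapolated = !crosses || icc < span[1] || icc > span[2],
               span = span))
  }
  if (length(concentration) < 4)
    warning("fewer than 4 concentrations; log-logistic fit may be unstable")
  # start from the interpolated crossing (or the median concentration)
  ic0 <- tryCatch(
    fitIC50(concentration, cummax(percent), method = "interp")@ic50,
    error = function(e) stats::median(concentration))
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- stats::median(concentration)
  dat <- data.frame(conc = concentration, pct = percent)
  fit <- minpack.lm::nlsLM(
    pct ~ 100 / (1 + (ic / conc)^h), data = dat,
    start = list(ic = ic0, h = 1),
    lower = c(1e-6, 0.05), upper = c(Inf, 20),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  new("Ic50Result", ic50 = unname(cf["ic"]),
      params = c(ic50 = unname(cf["ic"]), hill = unname(cf["h"])),
      residual = sum(stats::residuals(fit)^2), method = "loglogistic",
      extrapolated = !crosses || cf["ic"] < span[1] || cf["ic"] > span[2],
      span = span)
}

#' Fit an IC50 from a raw absorbance assay
#'
#' Converts absorbances to scavenging percentages with
#' [scavengingPercent()] and fits [fitIC50()].
#'
#' @param concentration ug/mL, ascending
#' @param aControl control absorbance at 521 nm
#' @param aSample per-concentration sample absorbances
#' @param method passed to [fitIC50()]
#' @return an [Ic50Result-class]
#' @export
fitIC50Assay <- function(concentration, aControl, aSample,
                         method = "loglogistic") {
  fitIC50(concentration, scavengingPercent(aControl, aSample),
          method = method)
}

#' Antioxidant attenuation report
#'
#' Compares the IC50 of the free antioxidant against the
#' protein-complexed one. A larger complexed IC50 (more compound needed
#' for the same effect) means the protein attenuates the antioxidant
#' capacity.
#'
#' @param freeResult,complexedResult [Ic50Result-class] objects under
#'   comparable conditions
#' @return list: `ic50_free`, `ic50_complexed`, `ratio`
#'   (complexed / free), `percent_change`, `direction` (`"attenuated"`,
#'   `"enhanced"` or `"unchanged"`)
#' @export
attenuationReport <- function(freeResult, complexedResult) {
  stopifnot(is(freeResult, "Ic50Result"), is(complexedResult, "Ic50Result"))
  f <- ic50(freeResult); c2 <- ic50(complexedResult)
  ratio <- c2 / f
  list(ic50_free = f, ic50_complexed = c2, ratio = ratio,
       percent_change = 100 * (c2 - f) / f,
       direction = if (c2 > f) "attenuated"
                   else if (c2 < f) "enhanced" else "unchanged")
}

#' Read a DPPH assay table
#'
#' Columns: `condition`, `concentration_ug_per_mL`, `absorbance`; rows
#' with concentration 0 define the control absorbance for their
#' condition (or a shared control when only one zero row exists).
#'
#' @param path delimited text file
#' @param sep delimiter
#' @return named list (per condition) of lists with `concentration`,
#'   `a_control`, `a_sample`
#' @export
readDpphTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("condition", "concentration_ug_per_mL", "absorbance")
  if (!all(need %in% names(df)))
    stop("DPPH table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  zero <- df[df$concentration_ug_per_mL == 0, ]
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond & df$concentration_ug_per_mL > 0, ]
    sub <- sub[order(sub$concentration_ug_per_mL), ]
    ctrl <- zero$absorbance[zero$condition == cond]
    if (!length(ctrl)) ctrl <- zero$absorbance
    if (!length(ctrl)) stop("no zero-concentration control row for ", cond)
    out[[cond]] <- list(concentration = sub$concentration_ug_per_mL,
                        a_control = ctrl[1], a_sample = sub$absorbance)
  }
  out
}
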