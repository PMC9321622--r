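#' @include AllClasses.R utils.R
NULL

#' Double-logarithm binding fit
#'
#' For a static quenching process the apparent binding constant Ka and
#' number of binding sites n follow from
#' lg((F0 - F)/F) = lg Ka + n lg \[Q\]: an ordinary least-squares line
#' on the base-10 log-log scale, with n the slope and Ka = 10^intercept.
#' Points with F >= F0 (negative quench from noise) have no defined
#' logarithm and are dropped with a warning rather than clamped. The Ka
#' standard deviation is propagated from the intercept standard error:
#' SD(Ka) = Ka * ln(10) * SE(intercept).
#'
#' @param series a [TitrationSeries-class]
#' @param label free-text tag carried into the result (e.g. marker name)
#' @return a [BindingFit-class]
#' @examples
#' q <- seq(2.5e-6, 2.5e-5, 2.5e-6)
#' f0 <- 1000; f <- f0 / (1 + 1e4 * q)
#' fit <- doubleLogFit(TitrationSeries(q, f, F0 = f0))
#' c(bindingConstant(fit), bindingSites(fit))  # 1e4, 1
#' @export
doubleLogFit <- function(series, label = "") {
  stopifnot(is(series, "TitrationSeries"))
  q <- series@concentration
  f <- series@intensity
  f0 <- series@F0
  use <- q > 0 & f < f0
  nDropped <- sum(q > 0 & f >= f0)
  if (nDropped > 0)
    warning(nDropped, " point(s) with F >= F0 dropped from double-log fit")
  if (sum(use) < 3)
    stop("double-log fit needs >= 3 points with F < F0 and [Q] > 0")
  x <- log10(q[use])
  y <- log10((f0 - f[use]) / f[use])
  ols <- .ols(x, y)
  ka <- 10^ols$intercept
  new("BindingFit", ka = ka, n = ols$slope, r = ols$r,
      kaSD = ka * log(10) * ols$intercept_se,
      temperature = series@temperature, label = label,
      nPoints = as.integer(sum(use)), nDropped = as.integer(nDropped))
}

#' Site-marker competition analysis
#'
#' Compares the apparent binding constant measured without any marker
#' (blank) against those measured with site markers bound (classically
#' warfarin for Sudlow Site I and ibuprofen for Site II of serum
#' albumin). The marker whose presence depresses Ka the most, provided
#' the decrease exceeds `decreaseThreshold`, identifies the shared
#' binding site; otherwise the site is "unresolved". The marker-to-site
#' map is configuration, not code.
#'
#' @param blankFit [BindingFit-class] without marker
#' @param markerFits named list of [BindingFit-class], one per marker
#' @param decreaseThreshold percent decrease needed to call a site
#'   (default 50)
#' @param siteMap named character vector mapping marker name to site label
#' @return a list with `markers` (data.frame: marker, ka,
#'   percent_decrease), `assigned_site`, `assigned_marker`,
#'   `threshold`, `ka_blank`
#' @examples
#' # Table-style inputs: blank Ka 22.74e4, warfarin 5.31e4 (-76.65 %),
#' # ibuprofen 19.93e4 (-12.36 %) assigns Site I.
#' @export
competitionAnalysis <- function(blankFit, markerFits,
                                decreaseThreshold = 50,
                                siteMap = c(warfarin = "Site I",
                                            ibuprofen = "Site II")) {
  stopifnot(is(blankFit, "BindingFit"), is.list(markerFits),
            length(markerFits) >= 1,
            all(vapply(markerFits, is, logical(1), "BindingFit")))
  if (is.null(names(markerFits)) || any(!nzchar(names(markerFits))))
    stop("markerFits must be a named list (marker names)")
  kaBlank <- bindingConstant(blankFit)
  if (kaBlank <= 0) stop("blank Ka must be > 0")
  temps <- vapply(markerFits, temperature, numeric(1))
  if (any(temps != temperature(blankFit)))
    warning("marker fits and blank fit are at different temperatures")
  kas <- vapply(markerFits, bindingConstant, numeric(1))
  dec <- 100 * (kaBlank - kas) / kaBlank
  tab <- data.frame(marker = names(markerFits), ka = kas,
                    percent_decrease = dec, row.names = NULL)
  winners <- which(dec >= max(dec) - 1e-12 & dec > decreaseThreshold)
  if (length(winners) == 1) {
    marker <- tab$marker[winners]
    site <- if (marker %in% names(siteMap)) unname(siteMap[marker])
            else paste0("site of ", marker)
  } else {
    if (length(winners) > 1)
      warning("tie between markers; site unresolved")
    marker <- NA_character_
    site <- "unresolved"
  }
  list(markers = tab, assigned_site = site, assigned_marker = marker,
       threshold = decreaseThreshold, ka_blank = kaBlank)
}
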