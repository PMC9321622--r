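#' @include AllClasses.R
NULL

# gas constant, J/mol/K
.RGAS <- 8.314

# Simple-linear-regression summary used by every fitting stage:
# slope/intercept, their standard errors, and the Pearson correlation.
.ols <- function(x, y) {
  if (length(x) < 2 || stats::var(x) == 0)
    stop("regression needs >= 2 points with non-constant x")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on numerically perfect fits; zero-variance y makes
  # the correlation undefined (NA) - both are legitimate here
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(intercept = cf[1, 1], slope = cf[2, 1],
       intercept_se = cf[1, 2], slope_se = cf[2, 2],
       r = suppressWarnings(stats::cor(x, y)), fit = fit)
}

# Trapezoid quadrature weights for a (possibly non-uniform) grid.
.trapWeights <- function(x) {
  n <- length(x)
  if (n < 2) stop("need >= 2 grid points")
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# Read a two-column delimited numeric table, reporting the first bad line.
# Returns a two-column numeric matrix. `sep = ""` means any whitespace.
.readTwoColumns <- function(path, sep = ",", comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                !startsWith(trimws(lines), comment))
  if (!length(keep)) stop("no data rows in ", path)
  split1 <- function(ln) {
    parts <- if (identical(sep, "")) strsplit(trimws(ln), "[ \t]+")[[1]]
             else strsplit(ln, sep, fixed = TRUE)[[1]]
    trimws(parts)
  }
  parsed <- lapply(lines[keep], split1)
  # optional single header line: only skipped when no field is numeric
  first <- suppressWarnings(as.numeric(parsed[[1]]))
  if (all(is.na(first))) { keep <- keep[-1]; parsed <- parsed[-1] }
  if (!length(keep)) stop("no numeric rows in ", path)
  out <- matrix(NA_real_, length(parsed), 2)
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (length(p) < 2)
      stop("parse error in ", path, " at line ", keep[i],
           ": fewer than 2 columns")
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (anyNA(v))
      stop("parse error in ", path, " at line ", keep[i],
           ": non-numeric value")
    out[i, ] <- v
  }
  out
}

# Write a results list as pretty JSON (units carried in field names).
.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Convert kilocalories to kilojoules
#'
#' Multiplies by the configured calorie factor. The default is the
#' international-table calorie, 4.1868 J/cal, so that -8.1 kcal/mol maps
#' to -33.91 kJ/mol.
#'
#' @param eKcal energy in kcal (any sign)
#' @param factor J per cal; 4.1868 (IT) by default, 4.184 for the
#'   thermochemical calorie
#' @return energy in kJ
#' @examples
#' kcalToKJ(-8.1)   # -33.91
#' @export
kcalToKJ <- function(eKcal, factor = 4.1868) {
  stopifnot(is.finite(eKcal), is.finite(factor), factor > 0)
  eKcal * factor
}
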