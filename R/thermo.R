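#' @include AllClasses.R utils.R
NULL

#' Van't Hoff analysis of binding constants
#'
#' Two-parameter Van't Hoff fit: ln Ka = -dH/(R T) + dS/R, ordinary
#' least squares of ln Ka on 1/T, assuming the enthalpy change is
#' temperature-independent over the fitted range. dH (kJ/mol) comes
#' from the slope, dS (J/mol/K) from the intercept. Per-temperature
#' Gibbs energies are reported by both routes the field uses:
#' dG = dH - T dS (the headline value, consistent with the fitted
#' parameters) and dG = -RT ln Ka (a per-temperature cross-check that
#' needs no fit); their discrepancy is a useful internal-consistency
#' diagnostic. The sign-rule force classification of
#' [classifyForces()] is attached.
#'
#' @param ka binding constants (L/mol), one per temperature
#' @param temperatures absolute temperatures (K), distinct, >= 2
#' @return a [ThermoResult-class]
#' @examples
#' th <- vantHoffFit(c(6.77e4, 5.77e4, 4.46e4), c(288, 298, 310))
#' deltaH(th)  # about -14.1 kJ/mol
#' deltaS(th)  # about 43.5 J/mol/K
#' @export
vantHoffFit <- function(ka, temperatures) {
  stopifnot(length(ka) == length(temperatures), length(ka) >= 2,
            all(ka > 0), all(temperatures > 0))
  if (anyDuplicated(temperatures)) stop("duplicate temperatures")
  ord <- order(temperatures)
  ka <- ka[ord]; temperatures <- temperatures[ord]
  ols <- .ols(1 / temperatures, log(ka))
  dH <- -ols$slope * .RGAS / 1000       # kJ/mol
  dS <- ols$intercept * .RGAS           # J/mol/K
  new("ThermoResult",
      dH = dH, dS = dS,
      dHse = ols$slope_se * .RGAS / 1000,
      dSse = ols$intercept_se * .RGAS,
      temperatures = temperatures,
      gibbs = gibbsEnergy(dH, dS, temperatures),
      gibbsFromKa = gibbsFromKa(ka, temperatures),
      rCorr = abs(ols$r),
      forceLabel = classifyForces(dH, dS))
}

#' Gibbs energy from enthalpy and entropy
#'
#' dG = dH - T dS, with dS converted from J/mol/K to kJ/mol/K.
#'
#' @param dH kJ/mol
#' @param dS J/mol/K
#' @param temperature K (vectorized)
#' @return dG in kJ/mol
#' @examples
#' gibbsEnergy(-14.12, 43.57, 298)  # about -27.10
#' @export
gibbsEnergy <- function(dH, dS, temperature) {
  stopifnot(all(temperature > 0))
  dH - temperature * dS / 1000
}

#' Gibbs energy directly from a binding constant
#'
#' dG = -R T ln Ka, in kJ/mol. Reported alongside the dH - T dS route;
#' on data generated exactly from a Van't Hoff law the two agree to
#' machine precision, and on real data their gap measures how well the
#' two-parameter model holds.
#'
#' @param ka binding constant(s), L/mol, > 0
#' @param temperature K (vectorized with `ka`)
#' @return dG in kJ/mol
#' @examples
#' gibbsFromKa(5.77e4, 298)  # about -27.16
#' @export
gibbsFromKa <- function(ka, temperature) {
  stopifnot(all(ka > 0), all(temperature > 0))
  -.RGAS * temperature * log(ka) / 1000
}

#' Dominant-force classification from thermodynamic signs
#'
#' Sign-rule mapping (Ross-Subramanian style) of (dH, dS) to the
#' dominant non-covalent interaction:
#' dH < 0, dS > 0: electrostatic (with hydrophobic contribution);
#' dH > 0, dS > 0: hydrophobic;
#' dH < 0, dS < 0: hydrogen bonding / van der Waals;
#' a zero on either axis: indeterminate.
#'
#' @param dH kJ/mol
#' @param dS J/mol/K
#' @return character label
#' @examples
#' classifyForces(-14.12, 43.57)
#' @export
classifyForces <- function(dH, dS) {
  stopifnot(is.finite(dH), is.finite(dS))
  if (dH == 0 || dS == 0) return("indeterminate")
  if (dH < 0 && dS > 0) return("electrostatic (with hydrophobic contribution)")
  if (dH > 0 && dS > 0) return("hydrophobic")
  if (dH < 0 && dS < 0) return("hydrogen bonding / van der Waals")
  # dH > 0, dS < 0: binding would be non-spontaneous at all T
  "unfavorable (dH > 0, dS < 0)"
}
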