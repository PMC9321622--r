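#' @include AllClasses.R utils.R spectra.R thermo.R
NULL

# The generator defaults mirror the serum-albumin titration design the
# package targets: 2.5e-6 M protein, quencher 0 to 2.5e-5 M in 2.5e-6 M
# steps, excitation 280 nm, emission band near 327 nm, temperatures
# 288/298/310 K, and a binding law with dH = -14.12 kJ/mol and
# dS = 43.57 J/mol/K so that Ka(T) is a few 1e4 L/mol.

#' Simulate a fluorescence quenching titration
#'
#' Generates, for each temperature, a 1:1 static-quenching titration:
#' Ka(T) follows the Van't Hoff law exp(-dH/(RT) + dS/R) (or explicit
#' `ka` values), intensities obey (F0 - F)/F = Ka(T) \[Q\]^n, and each
#' emission spectrum is a Gaussian band whose center red-shifts
#' linearly with the titration step. Gaussian noise with standard
#' deviation `noise * F0` is added to every intensity channel. With
#' `noise = 0` every analysis stage recovers the generating parameters
#' exactly (the generator is a right-inverse of the fits).
#'
#' @param dH,dS binding enthalpy (kJ/mol) and entropy (J/mol/K) of the
#'   Ka(T) law
#' @param temperatures K
#' @param ka optional explicit Ka per temperature (overrides dH/dS)
#' @param n number of binding sites
#' @param concentrations quencher concentrations, mol/L (first may be 0)
#' @param F0 unquenched peak intensity, a.u.
#' @param center,width emission band center and Gaussian sigma, nm
#' @param redShiftPerStep band-center shift per titration step, nm
#' @param axis emission wavelength grid, nm
#' @param noise noise sigma as a fraction of `F0`
#' @param seed integer seed; the generated data are byte-identical for
#'   a fixed seed
#' @return list with `truth` (generating parameters), `series` (list of
#'   [TitrationSeries-class], one per temperature) and `spectra` (per
#'   temperature, a list of [Spectrum-class], one per concentration)
#' @examples
#' sim <- simulateTitration(noise = 0)
#' ksv(sternVolmerFit(sim$series[[2]]))  # = sim$truth$ka[2]
#' @export
simulateTitration <- function(dH = -14.12, dS = 43.57,
                              temperatures = c(288, 298, 310),
                              ka = NULL, n = 1,
                              concentrations = seq(0, 2.5e-5, by = 2.5e-6),
                              F0 = 1500, center = 327, width = 25,
                              redShiftPerStep = 0.2,
                              axis = seq(220, 500, by = 1),
                              noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ka))
    ka <- exp(-dH * 1000 / (.RGAS * temperatures) + dS / .RGAS)
  stopifnot(length(ka) == length(temperatures), all(ka > 0), n > 0,
            noise >= 0)
  truth <- list(dH = dH, dS = dS, temperatures = temperatures, ka = ka,
                n = n, F0 = F0, center = center, width = width,
                redShiftPerStep = redShiftPerStep, noise = noise,
                seed = seed)
  series <- list()
  spectra <- list()
  for (t in seq_along(temperatures)) {
    f <- F0 / (1 + ka[t] * concentrations^n)
    fNoisy <- f + stats::rnorm(length(f), 0, noise * F0)
    fNoisy <- pmax(fNoisy, F0 * 1e-6)  # intensities must stay positive
    specs <- vector("list", length(concentrations))
    for (i in seq_along(concentrations)) {
      mu <- center + redShiftPerStep * (i - 1)
      sig <- fNoisy[i] * exp(-(axis - mu)^2 / (2 * width^2)) +
        stats::rnorm(length(axis), 0, noise * F0)
      specs[[i]] <- Spectrum(axis, sig, kind = "emission",
                             label = sprintf("T=%gK [Q]=%.3g",
                                             temperatures[t],
                                             concentrations[i]))
    }
    f0obs <- if (concentrations[1] == 0) fNoisy[1] else F0
    series[[sprintf("%gK", temperatures[t])]] <-
      TitrationSeries(concentrations, fNoisy, F0 = f0obs,
                      temperature = temperatures[t])
    spectra[[sprintf("%gK", temperatures[t])]] <- specs
  }
  list(truth = truth, series = series, spectra = spectra)
}

#' Simulate a FRET donor/acceptor spectral pair
#'
#' Gaussian donor emission and Gaussian acceptor molar absorptivity on
#' a common grid, together with the reference overlap integral
#' evaluated by trapezoid quadrature on a grid `refine` times finer
#' (the oracle value against which [overlapIntegral()] is validated).
#'
#' @param donorCenter,donorSigma,donorAmp donor band parameters (nm, a.u.)
#' @param accCenter,accSigma,accPeak acceptor band parameters
#'   (nm, M^-1 cm^-1)
#' @param from,to,step wavelength grid, nm
#' @param refine refinement factor of the oracle grid
#' @return list: `donor`, `acceptor` ([Spectrum-class]), `jRef`
#'   (nm^4 M^-1 cm^-1), `truth`
#' @export
simulateFretPair <- function(donorCenter = 330, donorSigma = 20,
                             donorAmp = 1000,
                             accCenter = 340, accSigma = 25,
                             accPeak = 1e4,
                             from = 250, to = 450, step = 0.5,
                             refine = 10) {
  lam <- seq(from, to, by = step)
  donor <- Spectrum(lam, donorAmp * exp(-(lam - donorCenter)^2 /
                                          (2 * donorSigma^2)),
                    kind = "emission", label = "simulated donor")
  acceptor <- Spectrum(lam, accPeak * exp(-(lam - accCenter)^2 /
                                            (2 * accSigma^2)),
                       kind = "molar_absorptivity",
                       label = "simulated acceptor")
  fine <- seq(from, to, by = step / refine)
  fl <- donorAmp * exp(-(fine - donorCenter)^2 / (2 * donorSigma^2))
  ep <- accPeak * exp(-(fine - accCenter)^2 / (2 * accSigma^2))
  w <- .trapWeights(fine)
  jRef <- sum(fl * ep * fine^4 * w) / sum(fl * w)
  list(donor = donor, acceptor = acceptor, jRef = jRef,
       truth = list(donorCenter = donorCenter, donorSigma = donorSigma,
                    accCenter = accCenter, accSigma = accSigma,
                    accPeak = accPeak))
}

#' Simulate a circular-dichroism trace
#'
#' Builds an ellipticity trace with the double negative band (208 and
#' 222 nm) typical of helical proteins, scaled so that the 208 nm mean
#' residue ellipticity corresponds exactly to the requested alpha-helix
#' percentage through the two-anchor formula. [cdHelixContent()]
#' therefore recovers `alphaPercent` at zero noise.
#'
#' @param alphaPercent target alpha-helix content, percent
#' @param cp molar protein concentration (mol/L)
#' @param nRes residue count
#' @param pathLength cm
#' @param axis wavelength grid, nm (must contain 208)
#' @param noise noise sigma as a fraction of |theta(208)|
#' @param seed integer seed
#' @return list: `spectrum` ([Spectrum-class], mdeg), `truth`
#' @export
simulateCD <- function(alphaPercent = 59.24, cp = 2.5e-6, nRes = 585,
                       pathLength = 0.1, axis = seq(200, 240, by = 0.5),
                       noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(alphaPercent >= 0, alphaPercent <= 100)
  mre208 <- -(alphaPercent / 100 * (33000 - 4000) + 4000)
  theta208 <- mre208 * 10 * cp * nRes * pathLength   # mdeg
  shape <- exp(-(axis - 208)^2 / (2 * 6^2)) +
    0.9 * exp(-(axis - 222)^2 / (2 * 6^2))
  shape208 <- exp(0) + 0.9 * exp(-(222 - 208)^2 / (2 * 6^2))
  theta <- theta208 * shape / shape208
  theta <- theta + stats::rnorm(length(axis), 0, noise * abs(theta208))
  list(spectrum = Spectrum(axis, theta, kind = "ellipticity",
                           label = "simulated CD"),
       truth = list(alphaPercent = alphaPercent, mre208 = mre208,
                    theta208 = theta208, cp = cp, nRes = nRes,
                    pathLength = pathLength, noise = noise, seed = seed))
}

#' Simulate an amide-I FTIR envelope
#'
#' Sum of Gaussian component bands with prescribed area fractions on
#' the default amide-I assignment grid, plus optional linear baseline
#' and Gaussian noise. [amideBandFit()] recovers the fractions at zero
#' noise.
#'
#' @param fractions named area percentages; names must match
#'   `bandConfig$component`; they are normalized to sum to 100
#' @param bandConfig component table, see [amideBandConfig()]; only the
#'   components named in `fractions` are generated
#' @param sigmas Gaussian sigma per generated band, cm^-1
#' @param axis wavenumber grid, cm^-1
#' @param baseline `c(offset, slope)` of an additive linear baseline
#' @param noise noise sigma as a fraction of the envelope maximum
#' @param seed integer seed
#' @return list: `spectrum` ([Spectrum-class], kind `"ftir"`), `truth`
#' @export
simulateFTIR <- function(fractions = c(beta_sheet = 10.60,
                                       random_coil = 14.63,
                                       alpha_helix = 59.06,
                                       beta_turn = 13.86,
                                       beta_antiparallel = 1.85),
                         bandConfig = amideBandConfig(),
                         sigmas = c(9, 5, 7, 7, 4),
                         axis = seq(1600, 1700, by = 0.5),
                         baseline = c(0, 0), noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(fractions) %in% bandConfig$component),
            length(sigmas) == length(fractions))
  fractions <- 100 * fractions / sum(fractions)
  centers <- bandConfig$center[match(names(fractions),
                                     bandConfig$component)]
  amps <- fractions / (sigmas * sqrt(2 * pi))
  env <- rowSums(sapply(seq_along(fractions), function(i)
    amps[i] * exp(-(axis - centers[i])^2 / (2 * sigmas[i]^2))))
  env <- env + baseline[1] + baseline[2] * (axis - axis[1])
  env <- env + stats::rnorm(length(axis), 0, noise * max(env))
  list(spectrum = Spectrum(axis, env, kind = "ftir",
                           label = "simulated amide-I"),
       truth = list(fractions = fractions, centers = centers,
                    sigmas = sigmas, baseline = baseline, noise = noise,
                    seed = seed))
}

#' Simulate a DPPH scavenging assay
#'
#' Absorbances follow the log-logistic dose-response
#' percent = 100 / (1 + (IC50/c)^h) with a fixed control absorbance;
#' noise is added on the absorbance channel.
#'
#' @param ic50 ug/mL
#' @param hill Hill slope
#' @param concentration ug/mL, ascending
#' @param aControl control absorbance at 521 nm
#' @param noise noise sigma as a fraction of `aControl`
#' @param seed integer seed
#' @return list: `concentration`, `a_control`, `a_sample`, `truth`
#' @export
simulateDPPH <- function(ic50 = 9.653, hill = 1.2,
                         concentration = c(1, 5, 10, 20, 30, 40, 50),
                         aControl = 0.8, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ic50 > 0, hill > 0, aControl > 0)
  pct <- 100 / (1 + (ic50 / concentration)^hill)
  aSample <- aControl * (1 - pct / 100) +
    stats::rnorm(length(concentration), 0, noise * aControl)
  aSample <- pmax(aSample, 0)
  list(concentration = concentration, a_control = aControl,
       a_sample = aSample,
       truth = list(ic50 = ic50, hill = hill, aControl = aControl,
                    noise = noise, seed = seed))
}

#' Simulate an excitation-emission matrix
#'
#' Superimposes Gaussian fluorescence blobs on an (excitation,
#' emission) grid; the defaults emulate a serum-albumin landscape with
#' the Trp/Tyr peak at 280/330 nm and the polypeptide-backbone peak at
#' 230/330 nm on 5 nm steps.
#'
#' @param peaks data.frame with columns `ex`, `em`, `amp`
#' @param exAxis,emAxis grids, nm
#' @param sigmaEx,sigmaEm blob widths, nm
#' @param noise noise sigma as a fraction of the maximum amplitude
#' @param seed integer seed
#' @return list: `eem` ([EEMatrix-class]), `truth`
#' @export
simulateEEM <- function(peaks = data.frame(ex = c(280, 230),
                                           em = c(330, 330),
                                           amp = c(1539, 623.2)),
                        exAxis = seq(220, 400, by = 5),
                        emAxis = seq(220, 500, by = 5),
                        sigmaEx = 10, sigmaEm = 15,
                        noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(0, length(exAxis), length(emAxis))
  for (p in seq_len(nrow(peaks)))
    z <- z + peaks$amp[p] *
      outer(exp(-(exAxis - peaks$ex[p])^2 / (2 * sigmaEx^2)),
            exp(-(emAxis - peaks$em[p])^2 / (2 * sigmaEm^2)))
  if (noise > 0)
    z <- z + matrix(stats::rnorm(length(z), 0, noise * max(peaks$amp)),
                    nrow(z), ncol(z))
  list(eem = EEMatrix(exAxis, emAxis, z),
       truth = list(peaks = peaks, sigmaEx = sigmaEx, sigmaEm = sigmaEm,
                    noise = noise, seed = seed))
}

#' Write a full synthetic input bundle
#'
#' Emits, under `dir`, the same plain-text file formats the analysis
#' readers consume: a long-format titration table, donor/acceptor FRET
#' spectra, a CD trace, an FTIR spectrum, a DPPH assay table and an EEM
#' CSV, plus a JSON sidecar echoing every ground-truth parameter and
#' the seed.
#'
#' @param dir output directory (created if needed)
#' @param seed integer seed applied to every stochastic channel
#' @param noise shared noise fraction (default 0)
#' @return invisibly, a named list of the written paths
#' @export
simulateBundle <- function(dir, seed = 1, noise = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tit <- simulateTitration(noise = noise, seed = seed)
  writeTitrationTable(tit$series, p("titration.csv"))
  fret <- simulateFretPair()
  writeSpectrum(fret$donor, p("donor_emission.csv"))
  writeSpectrum(fret$acceptor, p("acceptor_epsilon.csv"))
  cd <- simulateCD(noise = noise, seed = seed + 1)
  writeSpectrum(cd$spectrum, p("cd.csv"))
  ftir <- simulateFTIR(noise = noise, seed = seed + 2)
  writeSpectrum(ftir$spectrum, p("ftir.csv"))
  dp1 <- simulateDPPH(noise = noise, seed = seed + 3)
  dp2 <- simulateDPPH(ic50 = 10.68, noise = noise, seed = seed + 4)
  df <- rbind(
    data.frame(condition = "free", concentration_ug_per_mL = 0,
               absorbance = dp1$a_control),
    data.frame(condition = "free",
               concentration_ug_per_mL = dp1$concentration,
               absorbance = dp1$a_sample),
    data.frame(condition = "complexed", concentration_ug_per_mL = 0,
               absorbance = dp2$a_control),
    data.frame(condition = "complexed",
               concentration_ug_per_mL = dp2$concentration,
               absorbance = dp2$a_sample))
  utils::write.csv(df, p("dpph.csv"), row.names = FALSE, quote = FALSE)
  eem <- simulateEEM(noise = noise, seed = seed + 5)
  writeEEM(eem$eem, p("eem.csv"))
  truth <- list(seed = seed, noise = noise, titration = tit$truth,
                fret = fret$truth, cd = cd$truth, ftir = ftir$truth,
                dpph_free = dp1$truth, dpph_complexed = dp2$truth,
                eem = eem$truth)
  .writeJson(truth, p("truth.json"))
  invisible(list(titration = p("titration.csv"),
                 donor = p("donor_emission.csv"),
                 acceptor = p("acceptor_epsilon.csv"),
                 cd = p("cd.csv"), ftir = p("ftir.csv"),
                 dpph = p("dpph.csv"), eem = p("eem.csv"),
                 truth = p("truth.json")))
}
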