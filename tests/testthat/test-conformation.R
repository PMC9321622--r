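test_that("synchronous profile recovers the generating slope and shift", {
  # programmed 0.5 nm red shift per step on a 0.5 nm grid so peak
  # positions are exact grid points: 10 steps give a 5 nm total shift
  ksvTrue <- 5e4
  sim <- simulateTitration(ka = ksvTrue, temperatures = 298,
                           redShiftPerStep = 0.5,
                           axis = seq(220, 500, 0.5), noise = 0)
  prof <- synchronousProfile(sim$spectra[[1]],
                             sim$series[[1]]@concentration,
                             deltaLambda = 60)
  expect_equal(prof$slope, ksvTrue, tolerance = 1e-9)
  expect_equal(prof$shift, 5)

  # a tyrosine-like channel with the weaker quenching and smaller shift
  sim15 <- simulateTitration(ka = 1e4, temperatures = 298,
                             redShiftPerStep = 0.3,
                             axis = seq(220, 500, 0.1), noise = 0)
  prof15 <- synchronousProfile(sim15$spectra[[1]],
                               sim15$series[[1]]@concentration,
                               deltaLambda = 15)
  expect_equal(prof15$shift, 3, tolerance = 1e-9)
  expect_lt(prof15$slope, prof$slope)  # Trp channel quenches faster
})

test_that("identical spectra across concentrations give zero slope and shift", {
  s <- gaussSpectrum()
  prof <- synchronousProfile(list(s, s, s, s), c(0, 1e-6, 2e-6, 3e-6))
  expect_lt(abs(prof$slope), 1e-6)  # numerically zero on the 1e-6 M scale
  expect_equal(prof$shift, 0)
})

test_that("mean residue ellipticity normalizes by 10 cp n l", {
  # unit identity
  expect_equal(meanResidueEllipticity(10 * 2e-6 * 585 * 0.1,
                                      cp = 2e-6), 1)
  # doubling the path length halves MRE
  m1 <- meanResidueEllipticity(-30, cp = 2.5e-6, pathLength = 0.1)
  m2 <- meanResidueEllipticity(-30, cp = 2.5e-6, pathLength = 0.2)
  expect_equal(m2, m1 / 2)
  expect_error(meanResidueEllipticity(-30, cp = 0))
})

test_that("alpha-helix formula is exact at both anchors and affine between", {
  expect_equal(alphaHelixFraction(-4000), 0)
  expect_equal(alphaHelixFraction(-33000), 100)
  # derived from the published CD composition (59.24 % helix)
  expect_equal(alphaHelixFraction(-21180), 59.24, tolerance = 1e-4)
  # affine: midpoint of two MREs maps to midpoint of percentages
  a <- alphaHelixFraction(-10000); b <- alphaHelixFraction(-20000)
  expect_equal(alphaHelixFraction(-15000), (a + b) / 2)
  expect_warning(out <- alphaHelixFraction(-40000), "clamped")
  expect_equal(out, 100)
})

test_that("CD chain: simulated trace returns the target helix content", {
  sim <- simulateCD(alphaPercent = 59.24, cp = 2.5e-6)
  res <- cdHelixContent(sim$spectrum, cp = 2.5e-6)
  expect_equal(unname(structureFractions(res)["alpha_helix"]), 59.24,
               tolerance = 1e-9)
  # the trace has the expected negative ellipticity at 208 nm
  expect_equal(sim$truth$theta208, -30.98, tolerance = 1e-3)
  sim2 <- simulateCD(alphaPercent = 30)
  expect_equal(unname(structureFractions(
    cdHelixContent(sim2$spectrum, cp = 2.5e-6))["alpha_helix"]), 30,
    tolerance = 1e-9)
})

test_that("amide-I decomposition: single and two-band recovery", {
  cfg <- amideBandConfig()
  # single band at 1654: 100% alpha-helix
  s1 <- simulateFTIR(fractions = c(alpha_helix = 100), sigmas = 7)
  r1 <- amideBandFit(s1$spectrum, cfg[cfg$component == "alpha_helix", ])
  expect_equal(unname(structureFractions(r1)), 100)

  # two bands (alpha 60 / beta-sheet 40) with 0.1% noise: within 2 points
  s2 <- simulateFTIR(fractions = c(beta_sheet = 40, alpha_helix = 60),
                     sigmas = c(9, 7), noise = 0.001, seed = 11)
  r2 <- amideBandFit(s2$spectrum,
                     cfg[cfg$component %in% c("beta_sheet", "alpha_helix"), ])
  expect_lt(max(abs(structureFractions(r2) - c(40, 60))), 2)

  # fractions always sum to 100 by construction
  expect_equal(sum(structureFractions(r2)), 100)
})

test_that("amide-I five-band decomposition is exact at zero noise", {
  sim <- simulateFTIR(noise = 0)
  res <- amideBandFit(sim$spectrum)
  expect_lt(max(abs(structureFractions(res) - sim$truth$fractions)), 1e-4)
  expect_equal(sum(structureFractions(res)), 100)
  # an additive linear baseline does not corrupt the fractions
  simB <- simulateFTIR(noise = 0, baseline = c(0.3, 0.002))
  resB <- amideBandFit(simB$spectrum)
  expect_lt(max(abs(structureFractions(resB) - simB$truth$fractions)),
            0.05)
})

test_that("amide-I fit input contracts", {
  short <- Spectrum(seq(1620, 1680, 2), rep(1, 31), kind = "ftir")
  expect_error(amideBandFit(short), "cover")
  notFtir <- gaussSpectrum()
  expect_error(amideBandFit(notFtir))
})
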