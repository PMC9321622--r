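test_that("transfer efficiency is 1 - F/F0 with domain checks", {
  expect_equal(transferEfficiency(0.8426, 1), 0.1574)
  expect_equal(transferEfficiency(5, 5), 0)
  expect_equal(transferEfficiency(0.5, 1), 0.5)
  expect_error(transferEfficiency(1.1, 1), "negative")
  expect_error(transferEfficiency(0.5, 0))
})

test_that("overlap integral matches the fine-grid quadrature oracle", {
  pair <- simulateFretPair(donorCenter = 330, donorSigma = 20,
                           accCenter = 340, accSigma = 25,
                           accPeak = 1e4, step = 0.5)
  ov <- overlapIntegral(pair$donor, pair$acceptor)
  expect_lt(abs(ov$j - pair$jRef) / pair$jRef, 1e-3)
  expect_equal(ov$units, "nm4.M-1.cm-1")
})

test_that("overlap integral converges at second order in grid spacing", {
  jAt <- function(step) {
    pair <- simulateFretPair(step = step)
    abs(overlapIntegral(pair$donor, pair$acceptor)$j - pair$jRef)
  }
  e2 <- jAt(2); e1 <- jAt(1)
  # halving the spacing should cut the error by about 4
  expect_gt(e2 / e1, 3)
})

test_that("overlap integral limiting and degenerate cases", {
  # zero acceptor absorptivity: J = 0
  lam <- seq(300, 400, 0.5)
  donor <- Spectrum(lam, exp(-(lam - 330)^2 / 800), kind = "emission")
  zeroAcc <- Spectrum(lam, rep(0, length(lam)),
                      kind = "molar_absorptivity")
  expect_equal(overlapIntegral(donor, zeroAcc)$j, 0)

  # delta-like donor band at l0: J -> eps(l0) * l0^4
  l0 <- 350; eps0 <- 1e4
  accFlat <- Spectrum(lam, rep(eps0, length(lam)),
                      kind = "molar_absorptivity")
  narrow <- Spectrum(lam, exp(-(lam - l0)^2 / (2 * 0.5^2)),
                     kind = "emission")
  jn <- overlapIntegral(narrow, accFlat)$j
  expect_equal(jn, eps0 * l0^4, tolerance = 1e-4)

  # disjoint ranges error
  far <- Spectrum(500:600, rep(1, 101), kind = "molar_absorptivity")
  expect_error(overlapIntegral(donor, far), "overlap")
})

test_that("J is invariant under donor rescaling; cm convention rescales units", {
  pair <- simulateFretPair()
  scaled <- Spectrum(axisValues(pair$donor),
                     signalValues(pair$donor) * 123.4, kind = "emission")
  expect_equal(overlapIntegral(scaled, pair$acceptor)$j,
               overlapIntegral(pair$donor, pair$acceptor)$j,
               tolerance = 1e-12)
  ovCm <- overlapIntegral(pair$donor, pair$acceptor, lambdaUnit = "cm")
  expect_equal(ovCm$units, "cm3.L.mol-1")
  # lambda^4 in cm^4 = (1e-7)^4 nm^-4, and dl contributes another 1e-7
  expect_equal(ovCm$j,
               overlapIntegral(pair$donor, pair$acceptor)$j * 1e-28,
               tolerance = 1e-9)
})

test_that("Forster radius follows the standard closed form and scaling laws", {
  cfg <- fretConfig()
  expect_equal(forsterRadius(0, cfg), 0)
  j <- 1e13
  expected_A <- (8.79e-5 * (2 / 3) * 1.336^-4 * 0.118 * j)^(1 / 6)
  expect_equal(forsterRadius(j, cfg), expected_A / 10, tolerance = 1e-12)
  # doubling the quantum yield multiplies R0 by 2^(1/6)
  cfg2 <- fretConfig(phi = 0.236)
  expect_equal(forsterRadius(j, cfg2) / forsterRadius(j, cfg), 2^(1 / 6),
               tolerance = 1e-12)
  expect_error(forsterRadius(-1, cfg), "negative")
})

test_that("distance inversion reproduces the published albumin values", {
  r <- donorAcceptorDistance(0.1574, 2.3749)
  expect_equal(r, 3.1411, tolerance = 5e-5)
  expect_equal(donorAcceptorDistance(0.5, 4), 4)
  expect_error(donorAcceptorDistance(0, 2), "strictly")
  expect_error(donorAcceptorDistance(1, 2), "strictly")
})

test_that("efficiency and distance are mutual inverses; r decreases in E", {
  r0 <- 2.3749
  for (e in c(0.01, 0.1574, 0.5, 0.9, 0.999)) {
    r <- donorAcceptorDistance(e, r0)
    eBack <- r0^6 / (r0^6 + r^6)
    expect_lt(abs(eBack - e), 1e-12)
  }
  rr <- vapply(seq(0.05, 0.95, 0.05), donorAcceptorDistance,
               numeric(1), r0 = r0)
  expect_true(all(diff(rr) < 0))
})

test_that("validity flags apply the 7 nm and 0.5-1.5 R0 rules strictly", {
  expect_equal(fretValidity(3.1411, 2.3749),
               c(valid_distance = TRUE, valid_ratio = TRUE))
  expect_equal(fretValidity(8, 2.3749),
               c(valid_distance = FALSE, valid_ratio = FALSE))
  # boundary is strict
  expect_false(fretValidity(1.5 * 2.0, 2.0)["valid_ratio"])
  expect_false(fretValidity(0.5 * 2.0, 2.0)["valid_ratio"])
})

test_that("the full chain returns an internally consistent FretResult", {
  pair <- simulateFretPair()
  res <- fretAnalysis(0.8426, 1, pair$donor, pair$acceptor)
  expect_s4_class(res, "FretResult")
  expect_equal(res@efficiency, 0.1574)
  # stored triplet satisfies E = R0^6 / (R0^6 + r^6) (validity contract)
  expect_equal(res@r0^6 / (res@r0^6 + res@distance^6), res@efficiency,
               tolerance = 1e-9)
})
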