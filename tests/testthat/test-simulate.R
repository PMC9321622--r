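test_that("generators are deterministic under a fixed seed", {
  a <- simulateTitration(noise = 0.01, seed = 42)
  b <- simulateTitration(noise = 0.01, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$series[[1]]@intensity,
    simulateTitration(noise = 0.01, seed = 43)$series[[1]]@intensity))

  d1 <- simulateDPPH(noise = 0.01, seed = 7)
  d2 <- simulateDPPH(noise = 0.01, seed = 7)
  expect_identical(d1, d2)
})

test_that("titration generator Ka(T) tracks the published triplet within 3%", {
  sim <- simulateTitration(dH = -14.12, dS = 43.57,
                           temperatures = c(288, 298, 310), noise = 0)
  published <- c(6.77e4, 5.77e4, 4.46e4)
  expect_true(all(abs(sim$truth$ka - published) / published < 0.03))
})

test_that("each generator is a right-inverse of its analysis at zero noise", {
  # titration -> Stern-Volmer and double-log fits
  sim <- simulateTitration(noise = 0)
  for (i in seq_along(sim$series)) {
    expect_lt(abs(ksv(sternVolmerFit(sim$series[[i]])) -
                  sim$truth$ka[i]) / sim$truth$ka[i], 1e-9)
    fit <- doubleLogFit(sim$series[[i]])
    expect_lt(abs(bindingConstant(fit) - sim$truth$ka[i]) /
              sim$truth$ka[i], 1e-9)
    expect_lt(abs(bindingSites(fit) - 1), 1e-9)
  }
  # titration -> Van't Hoff
  kas <- vapply(sim$series, function(s) bindingConstant(doubleLogFit(s)),
                numeric(1))
  th <- vantHoffFit(kas, sim$truth$temperatures)
  expect_equal(deltaH(th), sim$truth$dH, tolerance = 1e-9)
  expect_equal(deltaS(th), sim$truth$dS, tolerance = 1e-9)

  # FRET pair -> overlap integral (0.1% against the analytic oracle)
  pair <- simulateFretPair()
  expect_lt(abs(overlapIntegral(pair$donor, pair$acceptor)$j - pair$jRef) /
            pair$jRef, 1e-3)

  # CD -> helix content
  cd <- simulateCD(alphaPercent = 42.5)
  expect_equal(unname(structureFractions(
    cdHelixContent(cd$spectrum, cp = 2.5e-6))["alpha_helix"]), 42.5,
    tolerance = 1e-9)

  # DPPH -> interpolated IC50 on noiseless data
  dp <- simulateDPPH(ic50 = 10, noise = 0)
  pct <- scavengingPercent(dp$a_control, dp$a_sample)
  expect_equal(ic50(fitIC50(dp$concentration, pct, method = "interp")),
               10, tolerance = 0.2)
  expect_equal(ic50(fitIC50(dp$concentration, pct)), 10,
               tolerance = 1e-6)
})

test_that("emission spectra carry the programmed band and red shift", {
  sim <- simulateTitration(noise = 0, redShiftPerStep = 1,
                           axis = seq(220, 500, 1))
  specs <- sim$spectra[[1]]
  pos <- vapply(specs, function(s) unname(peakOf(s)["position"]),
                numeric(1))
  expect_equal(pos, 327 + 0:(length(specs) - 1))
  expect_equal(unname(peakOf(specs[[1]])["intensity"]), sim$truth$F0)
})

test_that("the synthetic bundle writes every consumable input plus truth", {
  dir <- tempfile()
  paths <- simulateBundle(dir, seed = 5)
  expect_true(all(file.exists(unlist(paths))))
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$seed, 5)
  # written files re-read into the objects the generators produced
  series <- readTitrationTable(paths$titration)
  expect_length(series, 3)
  expect_s4_class(readSpectrum(paths$cd, kind = "ellipticity"), "Spectrum")
})
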