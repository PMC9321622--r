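test_that("delimited spectra parse, normalize orientation, and round-trip", {
  p <- tmpText(c("280,100", "281,99"))
  s <- readSpectrum(p, kind = "emission")
  expect_s4_class(s, "Spectrum")
  expect_length(s, 2)
  expect_equal(axisValues(s), c(280, 281))
  expect_equal(signalValues(s), c(100, 99))

  # decreasing wavenumber axis is reversed together with the signal
  p2 <- tmpText(c("1700,0.5", "1650,0.7", "1600,0.2"))
  s2 <- readSpectrum(p2, kind = "ftir")
  expect_equal(axisValues(s2), c(1600, 1650, 1700))
  expect_equal(signalValues(s2), c(0.2, 0.7, 0.5))
  expect_match(spectrumLabel(s2), "reversed")

  # header line tolerated; whitespace dialect supported
  p3 <- tmpText(c("wavelength\tsignal", "300\t1", "301\t2"), ext = ".tsv")
  expect_equal(axisValues(readSpectrum(p3, sep = "\t")), c(300, 301))

  # full-precision round trip
  s4 <- gaussSpectrum()
  p4 <- tempfile()
  writeSpectrum(s4, p4)
  s5 <- readSpectrum(p4)
  expect_identical(axisValues(s5), axisValues(s4))
  expect_identical(signalValues(s5), signalValues(s4))
})

test_that("spectrum parsing errors name the offending line", {
  bad <- tmpText(c("280,100", "281,abc", "282,98"))
  expect_error(readSpectrum(bad), "line 2")
  expect_error(readSpectrum(tmpText("300,1")), "at least 2")
  expect_error(readSpectrum(tempfile()), "not found")
})

test_that("Spectrum validity enforces the container invariants", {
  expect_error(Spectrum(c(1, 1, 2), c(1, 2, 3)), "strictly increasing")
  expect_error(Spectrum(1:3, 1:2), "lengths differ")
  expect_error(Spectrum(1:3, c(-1, 0, 1), kind = "absorbance"), ">= 0")
  expect_error(Spectrum(1:3, 1:3, kind = "nope"), "kind")
})

test_that("peakOf is grid-based with ties toward the smaller axis value", {
  s <- gaussSpectrum(center = 327)
  pk <- peakOf(s)
  expect_equal(unname(pk["position"]), 327)
  expect_true(pk["position"] %in% axisValues(s))

  # window restriction
  pk2 <- peakOf(s, window = c(360, 500))
  expect_equal(unname(pk2["position"]), 360)

  # flat signal: smallest axis value wins
  flat <- Spectrum(1:10, rep(5, 10))
  expect_equal(unname(peakOf(flat)["position"]), 1)

  expect_error(peakOf(s, window = c(600, 700)), "no axis points")
})

test_that("shiftMetrics reproduces reported intensity decreases", {
  a <- gaussSpectrum()
  expect_equal(shiftMetrics(a, a), c(shift = 0, percent_decrease = 0))

  ref <- gaussSpectrum(center = 330, amp = 1539)
  per <- gaussSpectrum(center = 320, amp = 1291)
  m <- shiftMetrics(ref, per)
  expect_equal(unname(m["shift"]), -10)
  expect_equal(unname(m["percent_decrease"]), 16.11, tolerance = 1e-3)

  m2 <- shiftMetrics(gaussSpectrum(amp = 623.2),
                     gaussSpectrum(amp = 478.6))
  expect_equal(unname(m2["percent_decrease"]), 23.20, tolerance = 1e-3)

  expect_error(shiftMetrics(a, gaussSpectrum(kind = "ftir",
                                             axis = seq(220, 500, 1))),
               "share kind")
})

test_that("EEM peak finding excludes Rayleigh scatter and sorts by intensity", {
  sim <- simulateEEM()   # Trp/Tyr blob 280/330 amp 1539; backbone 230/330 amp 623.2
  pks <- findEEMPeaks(sim$eem, scatterHalfwidth = 15)
  expect_equal(nrow(pks), 2)
  expect_equal(pks$excitation, c(280, 230))
  expect_equal(pks$emission, c(330, 330))
  expect_equal(pks$stokes_shift, c(50, 100))
  expect_true(all(diff(pks$intensity) <= 0))
  expect_equal(pks$intensity, c(1539, 623.2), tolerance = 1e-2)

  # a blob centered on the first-order scatter diagonal is excluded
  diag <- simulateEEM(peaks = data.frame(ex = 300, em = 300, amp = 100),
                      sigmaEx = 5, sigmaEm = 5)
  expect_equal(nrow(findEEMPeaks(diag$eem, scatterHalfwidth = 10)), 0)

  # EEM CSV round trip
  p <- tempfile(fileext = ".csv")
  writeEEM(sim$eem, p)
  back <- readEEM(p)
  expect_equal(findEEMPeaks(back)$intensity, pks$intensity)
})
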