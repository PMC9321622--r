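test_that("Stern-Volmer fit recovers the generating constant exactly", {
  for (ksvTrue in c(5.7e4, 6.44e4, 1e3)) {
    fit <- sternVolmerFit(idealSeries(ksv = ksvTrue))
    expect_lt(abs(ksv(fit) - ksvTrue) / ksvTrue, 1e-9)
    expect_equal(fit@intercept, 1, tolerance = 1e-9)
    expect_equal(fit@r, 1, tolerance = 1e-9)
  }
})

test_that("Kq = Ksv / tau0 holds exactly and follows tau0", {
  fit <- sternVolmerFit(idealSeries(ksv = 6.44e4), tau0 = 1e-8)
  expect_identical(kq(fit), ksv(fit) / 1e-8)
  expect_equal(kq(fit), 6.44e12, tolerance = 1e-9)
  fit2 <- sternVolmerFit(idealSeries(ksv = 6.44e4), tau0 = 2e-8)
  expect_identical(kq(fit2), ksv(fit2) / 2e-8)
})

test_that("fit is invariant to uniform intensity rescaling", {
  s <- idealSeries(ksv = 5.7e4)
  scaled <- TitrationSeries(s@concentration, s@intensity * 37.5,
                            F0 = s@F0 * 37.5, temperature = s@temperature)
  expect_equal(ksv(sternVolmerFit(scaled)), ksv(sternVolmerFit(s)))
})

test_that("the zero-concentration point is excluded from the regression", {
  s <- idealSeries(ksv = 5e4)
  # corrupt the F0-point intensity: the fit must not change
  sNo0 <- TitrationSeries(s@concentration[-1], s@intensity[-1],
                          F0 = s@F0, temperature = s@temperature)
  expect_equal(ksv(sternVolmerFit(s)), ksv(sternVolmerFit(sNo0)))
})

test_that("Stern-Volmer fit rejects degenerate input", {
  expect_error(sternVolmerFit(
    TitrationSeries(c(1e-6, 2e-6), c(900, 800), F0 = 1000)),
    ">= 3")
  expect_error(TitrationSeries(c(0, 1e-6), c(1000, -5), F0 = 1000),
               "> 0")
  expect_error(TitrationSeries(c(2e-6, 1e-6), c(900, 950), F0 = 1000),
               "increasing")
})

test_that("mechanism classification applies trend and threshold jointly", {
  mkFit <- function(ksvVal, temp, tau0 = 1e-8)
    sternVolmerFit(idealSeries(ksv = ksvVal, temperature = temp),
                   tau0 = tau0)
  # decreasing Ksv(T), Kq >> 2e10: static
  fits <- list(mkFit(6.44e4, 288), mkFit(5.70e4, 298), mkFit(4.70e4, 310))
  res <- classifyQuenching(fits)
  expect_equal(res$mechanism, "static")
  expect_equal(res$ksv_trend, "decreasing")
  expect_true(res$kq_above_threshold)

  # Kq above threshold but Ksv increasing: conflicting evidence
  res2 <- classifyQuenching(list(mkFit(1.0e3, 288), mkFit(1.2e3, 310)))
  expect_equal(res2$mechanism, "indeterminate")

  # Kq at/below threshold with increasing Ksv: dynamic
  res3 <- classifyQuenching(list(mkFit(1.0e2, 288), mkFit(1.2e2, 310)))
  expect_equal(res3$mechanism, "dynamic")

  expect_error(classifyQuenching(list(mkFit(1e4, 298), mkFit(2e4, 298))),
               "duplicate")
})

test_that("titration tables round-trip through the long format", {
  sim <- simulateTitration(noise = 0)
  p <- tempfile(fileext = ".csv")
  writeTitrationTable(sim$series, p)
  back <- readTitrationTable(p)
  expect_equal(length(back), length(sim$series))
  for (nm in names(sim$series)) {
    expect_equal(back[[nm]]@concentration, sim$series[[nm]]@concentration)
    expect_equal(back[[nm]]@intensity, sim$series[[nm]]@intensity)
  }
})

test_that("inner-filter correction rescales intensities as 10^((Aex+Aem)/2)", {
  s <- idealSeries(ksv = 5e4)
  corr <- innerFilterCorrect(s, aEx = 0.1, aEm = 0.05)
  expect_equal(corr@intensity, s@intensity * 10^(0.075))
  expect_equal(corr@F0, s@F0)  # blank uncorrected by default
})
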