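test_that("double-log fit recovers Ka and n exactly on ideal data", {
  cases <- list(c(ka = 1e4, n = 1), c(ka = 5.77e4, n = 1),
                c(ka = 2e5, n = 1.3), c(ka = 5e3, n = 0.8))
  for (cs in cases) {
    fit <- doubleLogFit(idealSeries(ksv = cs["ka"], n = cs["n"]))
    expect_lt(abs(bindingConstant(fit) - cs["ka"]) / cs["ka"], 1e-9)
    expect_lt(abs(bindingSites(fit) - cs["n"]), 1e-9)
  }
})

test_that("with n = 1 the double-log Ka equals the Stern-Volmer Ksv", {
  s <- idealSeries(ksv = 5.7e4, n = 1)
  expect_equal(bindingConstant(doubleLogFit(s)),
               ksv(sternVolmerFit(s)), tolerance = 1e-9)
})

test_that("points with F >= F0 are dropped with a warning, not clamped", {
  q <- seq(0, 1e-5, 1e-6)
  f <- 1000 / (1 + 5e4 * q)
  f[3] <- 1001  # negative quench from noise
  s <- TitrationSeries(q, f, F0 = 1000)
  expect_warning(fit <- doubleLogFit(s), "dropped")
  expect_equal(fit@nDropped, 1L)
  # too few surviving points is a fit error
  s2 <- TitrationSeries(c(0, 1e-6, 2e-6, 3e-6),
                        c(1000, 1001, 1002, 1003), F0 = 1000)
  expect_error(suppressWarnings(doubleLogFit(s2)), ">= 3")
})

test_that("noiseless consistency: extra same-law points leave (Ka, n) fixed", {
  kaT <- 3e4; nT <- 1.1
  base <- idealSeries(ksv = kaT, n = nT, q = seq(0, 1e-5, 1e-6))
  ext <- idealSeries(ksv = kaT, n = nT, q = seq(0, 2.5e-5, 1.25e-6))
  f1 <- doubleLogFit(base); f2 <- doubleLogFit(ext)
  expect_equal(bindingConstant(f1), bindingConstant(f2), tolerance = 1e-9)
  expect_equal(bindingSites(f1), bindingSites(f2), tolerance = 1e-9)
})

test_that("Monte-Carlo recovery of Ka at 1% intensity noise is unbiased", {
  # 1% of F0 Gaussian noise on a Ka = 5.77e4 titration; the aggregate
  # (median across seeds) recovered Ka stays within 10% of truth
  kaT <- 5.77e4
  est <- vapply(1:200, function(s) {
    sim <- simulateTitration(ka = kaT, temperatures = 298, noise = 0.01,
                             seed = s)
    suppressWarnings(bindingConstant(doubleLogFit(sim$series[[1]])))
  }, numeric(1))
  expect_lt(abs(median(est) - kaT) / kaT, 0.10)
})

test_that("competition analysis reproduces marker-displacement percentages", {
  mkFit <- function(ka, label)
    doubleLogFit(idealSeries(ksv = ka, temperature = 298), label = label)
  blank <- mkFit(22.74e4, "blank")
  res <- competitionAnalysis(blank,
                             list(warfarin = mkFit(5.31e4, "warfarin"),
                                  ibuprofen = mkFit(19.93e4, "ibuprofen")))
  dec <- setNames(res$markers$percent_decrease, res$markers$marker)
  expect_equal(unname(dec["warfarin"]), 76.65, tolerance = 1e-3)
  expect_equal(unname(dec["ibuprofen"]), 12.36, tolerance = 1e-3)
  expect_equal(res$assigned_site, "Site I")
  expect_equal(res$assigned_marker, "warfarin")
})

test_that("competition percent decrease is scale-invariant and handles ties", {
  mkFit <- function(ka) doubleLogFit(idealSeries(ksv = ka))
  res1 <- competitionAnalysis(mkFit(2e4), list(m = mkFit(1e4)))
  res2 <- competitionAnalysis(mkFit(2e5), list(m = mkFit(1e5)))
  expect_equal(res1$markers$percent_decrease,
               res2$markers$percent_decrease)

  # marker equal to blank: 0% decrease, unresolved at any threshold
  same <- competitionAnalysis(mkFit(5e4), list(m = mkFit(5e4)),
                              decreaseThreshold = 0.001)
  expect_equal(same$markers$percent_decrease, 0, tolerance = 1e-9)
  expect_equal(same$assigned_site, "unresolved")

  # exact tie between two markers above threshold: unresolved + warning
  expect_warning(
    tie <- competitionAnalysis(mkFit(10e4),
                               list(a = mkFit(2e4), b = mkFit(2e4))),
    "tie")
  expect_equal(tie$assigned_site, "unresolved")
})
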