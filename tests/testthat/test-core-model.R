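test_that("overall labelling efficiency is the pooling-weighted mean", {
  expect_equal(overallLabellingEfficiency(
    experimentDesign(c(0.5, 0.5), c(1, 1), lam = 0.3)), 1.0)
  expect_equal(overallLabellingEfficiency(
    experimentDesign(c(0.5, 0.3, 0.2), c(0.9, 0.8, 0.7), lam = 0.3)), 0.83)
  expect_equal(overallLabellingEfficiency(
    experimentDesign(1.0, 0.0, lam = 0.3)), 0.0)
})

test_that("design validity rejects degenerate parameter sets", {
  expect_error(experimentDesign(c(0.6, 0.3), c(1, 1), 0.3), "sum to 1")
  expect_error(experimentDesign(c(0.5, 0.5), c(1.2, 1), 0.3), "\\[0, 1\\]")
  expect_error(experimentDesign(c(0.5, 0.5), c(1, 1), -1), "positive")
  expect_error(equalDesign(0, 0.9, 0.3), ">= 1")
  # a_i = 0 for one sample is allowed
  expect_s4_class(experimentDesign(c(0.5, 0.5), c(0, 1), 0.3),
                  "ExperimentDesign")
})

test_that("droplet occupancy pmf is the Poisson mass function", {
  expect_equal(dropletOccupancyPmf(0.3, 0), exp(-0.3))
  expect_equal(dropletOccupancyPmf(0.369, 1), 0.369 * exp(-0.369))
  expect_equal(sum(dropletOccupancyPmf(0.7, 0:50)), 1, tolerance = 1e-12)
  expect_error(dropletOccupancyPmf(0.3, -1), "nonnegative")
  expect_error(dropletOccupancyPmf(-0.3, 1), "positive")
})

test_that("class probabilities conserve mass over random designs", {
  set.seed(20)
  for (i in 1:1000) {
    d <- randomDesign()
    p <- classProbabilities(multipletProbabilities(d))
    expect_lt(abs(sum(p) - 1), 1e-12)
    lam <- loadingRate(d)
    expect_lt(abs(sum(p[c("hs", "ps", "mu", "un")]) -
                  (1 - exp(-lam) - lam * exp(-lam))), 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("closed forms match truncated-Poisson combinatorics oracle", {
  cases <- list(list(r = c(0.6, 0.4), a = c(0.9, 0.7), lam = 0.5),
                list(r = c(0.5, 0.3, 0.2), a = c(0.9, 0.8, 0.7), lam = 0.4),
                list(r = c(0.5, 0.5), a = c(1, 0.2), lam = 0.6))
  for (cs in cases) {
    want <- oracleClassProbs(cs$r, cs$a, cs$lam)
    got <- classProbabilities(
      multipletProbabilities(experimentDesign(cs$r, cs$a, cs$lam)))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("perfect labelling leaves only detectable or homogeneous multiplets", {
  d <- experimentDesign(c(0.3, 0.3, 0.4), c(1, 1, 1), lam = 0.8)
  p <- classProbabilities(multipletProbabilities(d))
  expect_equal(p[["ps"]], 0)
  expect_equal(p[["un"]], 0)
  expect_equal(p[["singlet_unlabelled"]], 0)
})

test_that("single fully-labelled sample makes every multiplet homogeneous", {
  lam <- 0.45
  p <- classProbabilities(multipletProbabilities(equalDesign(1, 1, lam)))
  expect_equal(p[["mu"]], 0)
  expect_equal(p[["hs"]], 1 - exp(-lam) - lam * exp(-lam), tolerance = 1e-14)
})

test_that("nothing labelled makes every multiplet unlabelled", {
  lam <- 0.45
  p <- classProbabilities(multipletProbabilities(equalDesign(2, 0, lam)))
  expect_equal(p[["hs"]], 0)
  expect_equal(p[["ps"]], 0)
  expect_equal(p[["mu"]], 0)
  expect_equal(p[["un"]], 1 - exp(-lam) - lam * exp(-lam), tolerance = 1e-14)
})

test_that("equal design reproduces the simplified closed forms", {
  set.seed(7)
  for (i in 1:50) {
    s <- sample.int(12, 1L)
    abar <- runif(1)
    lam <- runif(1, 0.05, 1.2)
    got <- classProbabilities(
      multipletProbabilities(equalDesign(s, abar, lam)))
    want <- equalCaseFormulas(s, abar, lam)
    for (cl in names(want))
      expect_lt(abs(got[[cl]] - want[[cl]]), 1e-12)
  }
  expect_equal(
    classProbabilities(multipletProbabilities(equalDesign(1, 1, 0.3))),
    classProbabilities(multipletProbabilities(experimentDesign(1, 1, 0.3))))
})

test_that("partial stealth at a well-labelled 8-sample design is small", {
  mp <- multipletProbabilities(equalDesign(8, 0.995, 0.369))
  expect_lt(classProbabilities(mp, "per_cell_droplet")[["ps"]], 0.002)
  expect_lt(multipletFractions(mp, "per_monolabelled")[["ps"]], 0.002)
})

test_that("convention conversions rescale by the right denominators", {
  d <- experimentDesign(c(0.5, 0.3, 0.2), c(0.9, 0.8, 0.7), 0.5)
  mp <- multipletProbabilities(d)
  p <- classProbabilities(mp)
  pc <- classProbabilities(mp, "per_cell_droplet")
  expect_equal(pc, p / (1 - exp(-0.5)))
  expect_equal(sum(pc[setdiff(names(pc), "empty")]), 1, tolerance = 1e-12)
  mono <- p[["singlet_labelled"]] + p[["hs"]] + p[["ps"]]
  pm <- classProbabilities(mp, "per_monolabelled")
  expect_equal(pm[["singlet_labelled"]] + pm[["hs"]] + pm[["ps"]], 1,
               tolerance = 1e-12)
  expect_equal(pm[["ps"]], p[["ps"]] / mono)
  fr <- multipletFractions(mp, "among_multiplets")
  expect_equal(sum(fr), 1, tolerance = 1e-12)
})

test_that("TSR closed form, identity, and limits hold", {
  # single fully-labelled sample: abar*lam*e^0 / (e^lam - 1)
  expect_equal(trueSingletRatio(equalDesign(1, 1, 0.5)),
               0.5 / (exp(0.5) - 1), tolerance = 1e-12)
  expect_equal(round(trueSingletRatio(equalDesign(1, 1, 0.5)), 5), 0.77075)
  # identity TSR = P(1)*abar / (P(1)*abar + p_hs + p_ps)
  set.seed(11)
  for (i in 1:200) {
    d <- randomDesign()
    if (overallLabellingEfficiency(d) == 0) next
    p <- classProbabilities(multipletProbabilities(d))
    p1a <- dropletOccupancyPmf(loadingRate(d), 1) *
      overallLabellingEfficiency(d)
    expect_lt(abs(trueSingletRatio(d) -
                  p1a / (p1a + p[["hs"]] + p[["ps"]])), 1e-12)
  }
  # many perfectly-labelled samples: TSR tends to 1
  expect_gt(trueSingletRatio(equalDesign(1e4, 1, 0.3)), 0.9999)
  # undefined with nothing labelled
  expect_error(trueSingletRatio(equalDesign(3, 0, 0.3)), "undefined")
})

test_that("multiplet composition responds monotonically to abar and lam", {
  abars <- seq(0.05, 1, by = 0.05)
  ps <- vapply(abars, function(ab)
    classProbabilities(multipletProbabilities(equalDesign(4, ab, 0.4))),
    numeric(7))
  expect_true(all(diff(ps["mu", ]) > 0))   # mu nondecreasing in abar
  expect_true(all(diff(ps["un", ]) < 0))   # un nonincreasing in abar
  # lam -> 0: all multiplet probabilities vanish
  tiny <- classProbabilities(multipletProbabilities(equalDesign(4, 0.9, 1e-8)))
  expect_true(all(tiny[c("hs", "ps", "mu", "un")] < 1e-15))
})

test_that("sweep tables carry normalised fractions and the design trends", {
  expect_error(sweepClassProportions("lam", numeric(0)), "empty")

  swA <- sweepClassProportions("labelling_efficiency",
                               grid = seq(0.05, 1, by = 0.05),
                               s = 5, lam = 0.3)
  expect_equal(rowSums(swA[, c("frac_hs", "frac_ps", "frac_mu", "frac_un")]),
               rep(1, nrow(swA)), tolerance = 1e-9)
  endA <- swA[swA$value == 1, ]
  expect_equal(endA$frac_ps, 0)
  expect_equal(endA$frac_un, 0)
  # partial stealth dominates multilabelled at low labelling efficiency
  lowA <- swA[swA$value <= 0.3, ]
  expect_true(all(lowA$frac_ps > lowA$frac_mu))

  swS <- sweepClassProportions("sample_count", grid = 2:20,
                               abar = 0.9, lam = 0.3)
  expect_true(all(diff(swS$frac_hs) < 0))  # hs falls with more samples
  expect_true(all(swS$frac_ps > 0.05))     # ps persists

  swL <- sweepClassProportions("lam", grid = seq(0.05, 2, by = 0.05),
                               s = 5, abar = 0.9)
  expect_true(all(diff(swL$p_multiplet) > 0))
})
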