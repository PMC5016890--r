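test_that("glEval matches the closed form and its hand-worked values", {
  expect_equal(glEval(glParams(1, 1, 0, 1), 0), 0.5)
  expect_equal(glEval(glParams(1, log(9), 1, 1), 0), 0.1)
  # agreement with the naive formula across random parameters and points
  set.seed(11)
  for (i in 1:30) {
    p <- glParams(Q = runif(1, .1, 8), B = runif(1, .2, 4),
                  M = runif(1, -3, 3), nu = runif(1, .2, 4))
    x <- runif(10, -10, 10)
    expect_equal(glEval(p, x),
                 naiveGL(glQ(p), glB(p), glM(p), glNu(p), x),
                 tolerance = 1e-12)
  }
})

test_that("glEval is strictly increasing, bounded in (0,1), and stable far out", {
  set.seed(12)
  for (i in 1:20) {
    p <- glParams(Q = runif(1, .1, 5), B = runif(1, .2, 3),
                  M = runif(1, -2, 2), nu = runif(1, .2, 3))
    # strictly increasing wherever the curve is away from saturation
    x <- sort(glM(p) + runif(50, -25, 25) / glB(p))
    v <- glEval(p, x)
    expect_true(all(diff(v) > 0))
    expect_true(all(v > 0 & v < 1))
    # and never outside (0,1) nor decreasing, however far out
    xf <- sort(runif(50, -1e4, 1e4))
    vf <- glEval(p, xf)
    expect_true(all(vf > 0 & vf < 1))
    expect_true(all(diff(vf) >= 0))
  }
  # asymptotes: approached but evaluation never overflows or leaves (0,1)
  p <- glParams(2, 1.5, 0, 0.8)
  far <- glEval(p, c(-5000, 5000))
  expect_true(all(is.finite(far)))
  expect_lt(far[1], 1e-300)
  expect_gt(far[1], 0)
  expect_equal(far[2], 1, tolerance = 1e-12)
  expect_lt(far[2], 1)
})

test_that("glEval and glInverse reject invalid input", {
  expect_error(glParams(-1, 1, 0, 1), "Q")
  expect_error(glParams(1, 0, 0, 1), "B")
  expect_error(glEval(glParams(1, 1, 0, 1), NA_real_), "finite")
  expect_error(glInverse(glParams(1, 1, 0, 1), 0), "strictly inside")
  expect_error(glInverse(glParams(1, 1, 0, 1), 1), "strictly inside")
})

test_that("glInverse inverts glEval", {
  expect_equal(glInverse(glParams(1, 1, 3, 1), 0.5), 3)
  expect_equal(glInverse(glParams(1, log(9), 1, 1), 0.1), 0, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:20) {
    p <- glParams(Q = runif(1, .1, 5), B = runif(1, .2, 3),
                  M = runif(1, -2, 2), nu = runif(1, .2, 3))
    u <- runif(10, 0.001, 0.999)
    expect_equal(glEval(p, glInverse(p, u)), u, tolerance = 1e-12)
  }
  expect_equal(glEval(glParams(1, 1, 0, 1), glInverse(glParams(1, 1, 0, 1), 0.37)),
               0.37, tolerance = 1e-12)
})

test_that("ecdfTable matches the brute-force indicator count", {
  tb <- ecdfTable(featureSample(c(1, 2, 3)))
  expect_equal(tb@points, c(1, 2, 3))
  expect_equal(tb@heights, c(1, 2, 3) / 3)
  tb2 <- ecdfTable(featureSample(c(5, 5, 5, 9)))
  expect_equal(tb2@points, c(5, 9))
  expect_equal(tb2@heights, c(3 / 4, 1))
  # exhaustive: every multiset of {1,2,3} up to size 8
  for (size in 1:8) {
    for (vals in allMultisets(c(1, 2, 3), size)) {
      tb <- ecdfTable(featureSample(vals))
      expect_equal(tb@heights, bruteEcdf(vals, tb@points))
      expect_equal(tb@heights[length(tb@heights)], 1)
      expect_true(all(abs(tb@heights * length(vals) -
                            round(tb@heights * length(vals))) < 1e-12))
    }
  }
  expect_error(featureSample(numeric(0)), "at least one")
})

test_that("glObjective sums squared residuals with multiplicity", {
  vals <- c(1, 2, 3)
  fs <- featureSample(vals)
  tb <- ecdfTable(fs)
  p <- glParams(1, 1, 2, 1)
  expected <- sum((naiveGL(1, 1, 2, 1, vals) - c(1, 2, 3) / 3)^2)
  expect_equal(glObjective(p, fs, tb), expected, tolerance = 1e-14)
  # duplicates counted with multiplicity
  fs2 <- featureSample(c(5, 5, 5, 9))
  tb2 <- ecdfTable(fs2)
  expected2 <- 3 * (naiveGL(1, 1, 6, 1, 5) - 0.75)^2 +
    (naiveGL(1, 1, 6, 1, 9) - 1)^2
  expect_equal(glObjective(glParams(1, 1, 6, 1), fs2, tb2), expected2)
  expect_gte(glObjective(glParams(0.3, 2, 0, 0.7), fs, tb), 0)
  # table must belong to the sample
  expect_error(glObjective(p, fs, tb2), "not derived")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(21)
  for (i in 1:25) {
    fs <- featureSample(rnorm(30, sd = runif(1, 0.5, 3)))
    tb <- ecdfTable(fs)
    p <- glParams(Q = runif(1, .2, 5), B = runif(1, .5, 3),
                  M = runif(1, -1, 1), nu = runif(1, .3, 3))
    g <- glGradient(p, fs, tb)
    fd <- fdGradient(p, fs, tb)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-3)), 1e-5)
  }
  # random 2-point case, same oracle
  fs <- featureSample(c(-0.4, 1.1))
  tb <- ecdfTable(fs)
  p <- glParams(1.3, 0.9, 0.2, 1.4)
  expect_lt(max(abs(glGradient(p, fs, tb) - fdGradient(p, fs, tb))), 1e-6)
})

test_that("initQ0 solves the anchor equation", {
  # symmetric spacing: exactly 1 for any width
  for (w in c(0.5, 1, 3, 10)) {
    q <- initQ0(-w, 0, w)
    expect_equal(q, 1, tolerance = 1e-9)
  }
  # asymmetric spacing: agrees with the independent bisection oracle
  for (anch in list(c(0, 1, 1.5), c(0, 1, 2.4), c(-2, 0, 1), c(1, 4, 8))) {
    q <- initQ0(anch[1], anch[2], anch[3])
    expect_equal(q, bisectQ0(anch[1], anch[2], anch[3]), tolerance = 1e-6)
    expect_lt(abs(q0AnchorResidual(q, anch[1], anch[2], anch[3])), 1e-10)
    expect_gt(q, 0)
  }
  expect_error(initQ0(0, 1, 1), "xMin < xMed < xMax")
})

test_that("initQ0 reports when the anchor equation has no root", {
  # spacing ratio 2 lies outside the solvable asymmetry band
  expect_error(initQ0(0, 1, 3), "no bracketing sign change")
  expect_error(initQ0(0, 2, 2.1), "no bracketing sign change")
})

test_that("initParams anchors the curve at 0.1 / 0.5 / 0.9", {
  fs <- featureSample(c(0, 0.5, 1, 1.5, 2))
  p <- initParams(fs)
  expect_equal(glQ(p), 1, tolerance = 1e-9)
  expect_equal(glNu(p), 1, tolerance = 1e-9)
  expect_equal(glB(p), log(9), tolerance = 1e-8)
  expect_equal(glM(p), 1)
  expect_equal(glEval(p, c(0, 1, 2)), c(0.1, 0.5, 0.9), tolerance = 1e-8)
  # the 0.5-at-median identity is algebraic: holds for any anchor triple,
  # and 0.1-at-minimum likewise; 0.9-at-maximum needs the solved Q0
  set.seed(31)
  for (i in 1:10) {
    v <- rnorm(41)
    fs <- featureSample(v)
    p <- initParams(fs)
    expect_equal(glEval(p, fs@xMed), 0.5, tolerance = 1e-12)
    expect_equal(glEval(p, fs@xMin), 0.1, tolerance = 1e-12)
  }
  expect_error(initParams(featureSample(c(1, 1, 1))), "degenerate")
})

test_that("fitGL descends from its initialization and converges", {
  set.seed(41)
  for (i in 1:5) {
    fs <- featureSample(rnorm(150, sd = runif(1, 0.5, 2)))
    fit <- fitGL(fs)
    rep <- fitReport(fit)
    expect_lte(rep@etaFinal, rep@etaInit)
    expect_gte(rep@etaFinal, 0)
    expect_true(rep@converged)
    p <- fittedParams(fit)
    expect_true(glQ(p) > 0 && glB(p) > 0 && glNu(p) > 0)
  }
})

test_that("fitGL reaches a first-order point", {
  set.seed(42)
  fs <- featureSample(rnorm(300))
  fit <- fitGL(fs)
  expect_lte(fitReport(fit)@gradNorm, 1e-4)
})

test_that("fitGL under a tiny budget warns and returns its best iterate", {
  set.seed(43)
  fs <- featureSample(rlnorm(200))
  expect_warning(fit <- fitGL(fs, control = fitGLControl(maxit = 1L)),
                 "budget")
  expect_false(fitReport(fit)@converged)
  expect_lte(fitReport(fit)@etaFinal, fitReport(fit)@etaInit)
  expect_error(fitGL(featureSample(rep(2, 5))), "degenerate")
})

test_that("transforming a sample by its own fitted curve is nearly uniform", {
  set.seed(44)
  fs <- featureSample(rnorm(5000))
  fit <- fitGL(fs)
  u <- glEval(fittedParams(fit), sampleValues(fs))
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u))) +
    0.5 / length(u)
  expect_lte(ks, 0.05)
})
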