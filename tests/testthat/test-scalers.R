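test_that("zscore and minmax store and apply the textbook maps", {
  x <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
  mz <- fitScaler(x, "zscore")
  rec <- featureRecord(mz, 1)
  expect_equal(rec$params$mean, 2)
  expect_equal(rec$params$sd, 1)   # n - 1 denominator
  expect_equal(as.numeric(applyScaler(mz, x)), c(-1, 0, 1))

  mm <- fitScaler(x, "minmax")
  expect_equal(featureRecord(mm, 1)$params, list(xMin = 1, xMax = 3))
  expect_equal(as.numeric(applyScaler(mm, x)), c(0, 0.5, 1))
  # out-of-range values are deliberately not clipped
  expect_equal(as.numeric(applyScaler(mm, matrix(5, ncol = 1))), 2.0)

  mn <- fitScaler(x, "none")
  expect_equal(applyScaler(mn, x), x)
})

test_that("degenerate features fall back instead of failing", {
  x <- cbind(const = rep(3, 20), ok = 1:20)
  for (m in c("minmax", "zscore", "gl")) {
    expect_warning(mod <- fitScaler(x, m), "fallback")
    expect_true(featureRecord(mod, 1)$fallback)
    expect_false(featureRecord(mod, 2)$fallback)
    out <- applyScaler(mod, x)
    expect_equal(out[, 1], rep(if (m == "gl") 0.5 else 0, 20))
  }
  # fewer than 3 distinct values cannot support a curve fit
  x2 <- cbind(two = rep(c(0, 1), 10))
  expect_warning(mod2 <- fitScaler(x2, "gl"), "distinct")
  expect_true(featureRecord(mod2, 1)$fallback)
})

test_that("zero-inflated features are fitted through quartile anchors", {
  set.seed(5)
  v <- c(rep(0, 70), rlnorm(30))   # median equals the minimum
  x <- matrix(v, ncol = 1, dimnames = list(NULL, "zi"))
  # a stiff fit like this may exhaust the iteration budget (flagged by a
  # warning); the returned best iterate must still scale correctly
  mod <- suppressWarnings(fitScaler(x, "gl"))
  expect_false(featureRecord(mod, 1)$fallback)
  out <- as.numeric(applyScaler(mod, x))
  expect_true(all(out > 0 & out < 1))
  expect_true(all(diff(out[order(v)][c(1, 71:100)]) > 0))
})

test_that("the GL map is bounded on any finite input, however extreme", {
  set.seed(6)
  x <- matrix(rnorm(100), ncol = 1)
  mod <- fitScaler(x, "gl")
  probe <- matrix(c(-1e6, -1e3, 0, 1e3, 1e6), ncol = 1)
  out <- as.numeric(applyScaler(mod, probe))
  expect_true(all(out > 0 & out < 1))
  expect_true(all(diff(out) >= 0))
  # strictly increasing away from double-precision saturation
  near <- matrix(seq(-10, 10, length.out = 9), ncol = 1)
  expect_true(all(diff(as.numeric(applyScaler(mod, near))) > 0))
})

test_that("every scaler preserves order; GL strictly on distinct inputs", {
  set.seed(7)
  x <- matrix(c(rnorm(60), rexp(60)), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  probe <- matrix(c(sort(rnorm(20, sd = 2)), sort(rexp(20))), ncol = 2)
  for (m in c("gl", "minmax", "zscore", "none")) {
    mod <- fitScaler(x, m)
    out <- applyScaler(mod, probe)
    expect_true(all(diff(out[, 1]) >= 0))
    expect_true(all(diff(out[, 2]) >= 0))
    if (m == "gl") expect_true(all(diff(out[, 1]) > 0))
  }
})

test_that("transforming test rows never consults other test rows", {
  set.seed(8)
  train <- matrix(rnorm(80), ncol = 2)
  test <- matrix(rnorm(40, sd = 3), ncol = 2)
  for (m in c("gl", "minmax", "zscore")) {
    mod <- fitScaler(train, m)
    full <- applyScaler(mod, test)
    corrupted <- test
    corrupted[-1, ] <- corrupted[-1, ] * 1e4 + 7   # mangle the other rows
    alone <- applyScaler(mod, corrupted)
    expect_identical(full[1, ], alone[1, ])
  }
})

test_that("model JSON round-trips bit-for-bit", {
  set.seed(9)
  x <- matrix(c(rnorm(50), rlnorm(50)), ncol = 2,
              dimnames = list(NULL, c("n", "ln")))
  probe <- matrix(rnorm(20, sd = 4), ncol = 2)
  for (m in c("gl", "minmax", "zscore", "none")) {
    mod <- suppressWarnings(fitScaler(x, m))   # budget warnings possible
    path <- withr::local_tempfile(fileext = ".json")
    writeScalerModel(mod, path)
    back <- readScalerModel(path)
    expect_identical(applyScaler(back, probe), applyScaler(mod, probe))
    if (m == "gl") {
      a <- featureRecord(mod, 1)$params
      b <- featureRecord(back, 1)$params
      expect_identical(unlist(a[c("Q", "B", "M", "nu")]),
                       unlist(b[c("Q", "B", "M", "nu")]))
    }
  }
})

test_that("malformed or invalid model files are rejected with clear errors", {
  set.seed(10)
  x <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "f"))
  mod <- fitScaler(x, "gl")
  path <- withr::local_tempfile(fileext = ".json")
  writeScalerModel(mod, path)

  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  broken <- doc; broken$features[[1]]$params[["Q"]] <- NULL
  p1 <- withr::local_tempfile()
  writeLines(jsonlite::toJSON(broken, auto_unbox = TRUE, digits = I(17)), p1)
  expect_error(readScalerModel(p1), "missing parameters")

  neg <- doc; neg$features[[1]]$params$Q <- -2
  p2 <- withr::local_tempfile()
  writeLines(jsonlite::toJSON(neg, auto_unbox = TRUE, digits = I(17)), p2)
  expect_error(readScalerModel(p2), "Q, B, nu > 0")

  old <- doc; old$format_version <- "0.9"
  p3 <- withr::local_tempfile()
  writeLines(jsonlite::toJSON(old, auto_unbox = TRUE, digits = I(17)), p3)
  expect_error(readScalerModel(p3), "incompatible")

  p4 <- withr::local_tempfile()
  writeLines("{not json", p4)
  expect_error(readScalerModel(p4), "malformed")
})

test_that("shape mismatches and missing values are rejected", {
  x <- matrix(rnorm(40), ncol = 2)
  mod <- fitScaler(x, "minmax")
  expect_error(applyScaler(mod, matrix(1, ncol = 3, nrow = 2)), "mismatch")
  xna <- x; xna[1, 1] <- NA
  expect_error(fitScaler(xna, "minmax"), "non-finite")
})
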