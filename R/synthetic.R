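# Seeded generators for every input the tests and demos need: distributional
# samples, outlier-contaminated samples, boundary-dense two-class 2-D data,
# and exact draws from a known generalized logistic CDF. All generators use
# one named RNG (Mersenne-Twister) so a given seed is bit-reproducible.

#' Draw a base distributional sample
#'
#' @param kind `"normal"`, `"lognormal"` (right-skewed) or `"heavy_tail"`
#'   (Student t with 3 degrees of freedom).
#' @param n sample size (>= 1).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param location,scale location/scale applied to the draw (meanlog/sdlog
#'   for `"lognormal"`).
#' @return A [FeatureSample-class].
#' @export
genSample <- function(kind = c("normal", "lognormal", "heavy_tail"),
                      n, seed, location = 0, scale = 1) {
  kind <- match.arg(kind)
  if (n < 1L) stop("'n' must be at least 1")
  if (scale <= 0) stop("'scale' must be positive")
  v <- withSeed(seed, switch(kind,
    normal = stats::rnorm(n, location, scale),
    lognormal = stats::rlnorm(n, location, scale),
    heavy_tail = location + scale * stats::rt(n, df = 3)))
  featureSample(v)
}

#' Sample from a known generalized logistic CDF
#'
#' Inverse-transform sampling: uniform draws pushed through [glInverse()],
#' so the draws have CDF exactly the curve `params`.
#'
#' @param params a [GLParams-class] object.
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @return A [FeatureSample-class] of n i.i.d. draws.
#' @examples
#' s <- sampleFromGL(glParams(1, 1, 0, 1), 100, seed = 7)
#' @export
sampleFromGL <- function(params, n, seed) {
  .checkParams(params)
  if (n < 1L) stop("'n' must be at least 1")
  u <- withSeed(seed, stats::runif(n))
  featureSample(glInverse(params, u))
}

#' Contaminate a sample with far-out outliers
#'
#' Appends `nOutliers` values at `base_max + magnitude * base_range` to a
#' base sample, emulating gross measurement errors. Each outlier raises the
#' empirical CDF of the original points by at most
#' `nOutliers / (n + nOutliers)`, which is the mechanism making the CDF map
#' robust to contamination.
#'
#' @param n base sample size.
#' @param kind,location,scale base distribution, as in [genSample()].
#' @param magnitude outlier offset as a multiple of the base range (> 0).
#' @param nOutliers number of appended outliers (>= 1, and < n/10).
#' @param seed integer seed.
#' @return A list with elements `sample` (a [FeatureSample-class] of length
#'   `n + nOutliers`), `isOutlier` (logical mask), and `base` (the clean
#'   [FeatureSample-class]).
#' @export
genContaminated <- function(n, magnitude, nOutliers = 1L, seed,
                            kind = "normal", location = 0, scale = 1) {
  if (magnitude <= 0) stop("'magnitude' must be positive")
  if (nOutliers < 1L) stop("'nOutliers' must be at least 1")
  if (nOutliers >= n / 10) stop("'nOutliers' must be below n/10")
  base <- genSample(kind, n, seed, location, scale)
  rng <- base@xMax - base@xMin
  out <- rep(base@xMax + magnitude * rng, nOutliers)
  list(sample = featureSample(c(base@values, out)),
       isOutlier = c(rep(FALSE, n), rep(TRUE, nOutliers)),
       base = base)
}

#' Two-class 2-D data dense near the decision boundary
#'
#' Generates two clusters on either side of the diagonal boundary
#' x1 + x2 = 0. Along the boundary-normal direction each class follows a
#' shifted log-normal whose density piles up toward the boundary (the
#' crowding that makes margins matter); the tangential coordinate is
#' standard normal. The classes are separated by a guaranteed gap of
#' `separation` along the normal, so they are linearly separable at any
#' positive separation, yet crowded for small ones.
#'
#' @param nPerClass samples per class (>= 10).
#' @param separation gap between the classes along the boundary normal (> 0).
#' @param boundaryDensity log-sd of the normal-direction log-normal; smaller
#'   values concentrate the classes harder against the boundary.
#' @param seed integer seed.
#' @return A list with `x` (a `2*nPerClass` by 2 numeric matrix) and
#'   `labels` (0/1 integer vector, balanced).
#' @export
genTwoClass <- function(nPerClass, separation = 1, boundaryDensity = 0.5,
                        seed = 1L) {
  if (nPerClass < 10L) stop("'nPerClass' must be at least 10")
  if (separation <= 0) stop("'separation' must be positive")
  withSeed(seed, {
    n <- as.integer(nPerClass)
    # distance from the boundary along the normal u = (1,1)/sqrt(2)
    aPos <- separation / 2 + stats::rlnorm(n, 0, boundaryDensity)
    aNeg <- -separation / 2 - stats::rlnorm(n, 0, boundaryDensity)
    tPos <- stats::rnorm(n)
    tNeg <- stats::rnorm(n)
    u <- c(1, 1) / sqrt(2)
    w <- c(-1, 1) / sqrt(2)
    x <- rbind(cbind(aNeg * u[1] + tNeg * w[1], aNeg * u[2] + tNeg * w[2]),
               cbind(aPos * u[1] + tPos * w[1], aPos * u[2] + tPos * w[2]))
    colnames(x) <- c("x1", "x2")
    list(x = x, labels = c(rep(0L, n), rep(1L, n)))
  })
}

#' Benchmark stress scenario: scale mismatch plus gross outliers
#'
#' Builds the two-class data of [genTwoClass()], then inflates the first
#' feature by a large factor and replaces the first feature of a few random
#' rows with a value far above its range — the combination under which the
#' bounded CDF map keeps both features usable while range-based scaling
#' squeezes the informative feature into a sliver.
#'
#' @param nPerClass samples per class.
#' @param seed integer seed.
#' @param inflate multiplicative scale mismatch applied to feature 1.
#' @param nOutliers number of corrupted rows.
#' @param outlierMagnitude outlier offset as a multiple of the (inflated)
#'   feature-1 range.
#' @param separation,boundaryDensity passed to [genTwoClass()].
#' @return A list with `x`, `labels` and `outlierRows`.
#' @export
genBenchmarkScenario <- function(nPerClass = 60L, seed = 1L, inflate = 1e6,
                                 nOutliers = 3L, outlierMagnitude = 100,
                                 separation = 1, boundaryDensity = 0.5) {
  d <- genTwoClass(nPerClass, separation, boundaryDensity, seed)
  x <- d$x
  x[, 1L] <- x[, 1L] * inflate
  rows <- withSeed(seed + 1L, sample.int(nrow(x), nOutliers))
  rng <- max(x[, 1L]) - min(x[, 1L])
  x[rows, 1L] <- max(x[, 1L]) + outlierMagnitude * rng
  list(x = x, labels = d$labels, outlierRows = rows)
}
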