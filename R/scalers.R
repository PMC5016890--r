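# Fitting and applying per-feature scaling models: the generalized logistic
# CDF map, min-max and z-score baselines, and a passthrough. Strict
# fit-on-train semantics: a model carries everything needed to transform
# unseen data and never consults it.

MODEL_FORMAT_VERSION <- "1.0"

#' Fit a scaling model to a training matrix
#'
#' Fits each feature independently. For `method = "gl"` a generalized
#' logistic curve is fitted to the feature's empirical CDF ([fitGL()]) and
#' later used as the scaling map; `"minmax"` stores the training minimum and
#' maximum; `"zscore"` the training mean and standard deviation (n-1
#' denominator); `"none"` is a passthrough.
#'
#' Degenerate features are flagged instead of raising: a constant feature
#' falls back for every method, and a feature whose median equals its
#' minimum (or maximum) — common in zero-inflated data — has that anchor
#' replaced by the 75th (25th) percentile for the curve initialization; if
#' still degenerate, the feature falls back. Fallback features transform to
#' the constant 0.5 for `"gl"` and 0 for `"minmax"`/`"zscore"`.
#'
#' @param x numeric training matrix or data.frame (samples x features),
#'   all values finite.
#' @param method one of `"gl"`, `"minmax"`, `"zscore"`, `"none"`.
#' @param control curve-fit settings from [fitGLControl()] (gl only).
#' @return A [ScalerModel-class].
#' @examples
#' set.seed(1)
#' x <- cbind(a = rnorm(50), b = rexp(50))
#' m <- fitScaler(x, "gl")
#' range(applyScaler(m, x))   # strictly inside (0, 1)
#' @export
fitScaler <- function(x, method = c("gl", "minmax", "zscore", "none"),
                      control = fitGLControl()) {
  method <- match.arg(method)
  x <- asFeatureMatrix(x)
  if (method %in% c("minmax", "zscore") && nrow(x) < 2L)
    stop("'minmax' and 'zscore' need at least two training samples")

  features <- lapply(seq_len(ncol(x)), function(j) {
    nm <- colnames(x)[j]
    v <- x[, j]
    rec <- list(name = nm, fallback = FALSE, params = list())
    switch(method,
      none = rec,
      minmax = {
        if (min(v) == max(v)) {
          warning(sprintf("feature '%s' is constant; flagged as fallback", nm))
          rec$fallback <- TRUE
        } else rec$params <- list(xMin = min(v), xMax = max(v))
        rec
      },
      zscore = {
        s <- stats::sd(v)
        if (s == 0) {
          warning(sprintf("feature '%s' is constant; flagged as fallback", nm))
          rec$fallback <- TRUE
        } else rec$params <- list(mean = mean(v), sd = s)
        rec
      },
      gl = {
        if (length(unique(v)) < 3L) {
          warning(sprintf(
            "feature '%s' has fewer than 3 distinct values; flagged as fallback", nm))
          rec$fallback <- TRUE
          return(rec)
        }
        fs <- featureSample(v)
        med <- fs@xMed
        if (med == fs@xMin) med <- stats::quantile(v, 0.75, names = FALSE)
        if (med == fs@xMax) med <- stats::quantile(v, 0.25, names = FALSE)
        if (med <= fs@xMin || med >= fs@xMax) {
          warning(sprintf(
            "feature '%s' has degenerate spacing; flagged as fallback", nm))
          rec$fallback <- TRUE
          return(rec)
        }
        init <- .initFromAnchors(fs@xMin, med, fs@xMax)
        # candidate starts are fitted quietly; only the selected fit's
        # convergence is reported
        fitGLQuiet <- function(...) suppressWarnings(fitGL(...))
        cands <- list(fitGLQuiet(fs, control = control, init = init))
        # second start from moment matching (symmetric logistic with the
        # slope of a normal of the same spread): guards against poor local
        # minima when the order-statistic anchors are unrepresentative,
        # e.g. zero-inflated features
        init2 <- glParams(Q = 1, B = 1.6 / stats::sd(v), M = mean(v), nu = 1)
        cands <- c(cands, fitGLQuiet(fs, control = control, init = init2))
        # third start: symmetric logistic through the ECDF at the quartiles
        # (logit-matched); reaches basins the other starts miss when a
        # point mass pins the ECDF far from 0.5 at an extreme
        q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
        if (q[2] > q[1]) {
          n <- length(v)
          h <- pmin(pmax(stats::ecdf(v)(q), 1 / (n + 1)), n / (n + 1))
          lgt <- log(h / (1 - h))
          if (lgt[2] > lgt[1]) {
            b3 <- (lgt[2] - lgt[1]) / (q[2] - q[1])
            init3 <- glParams(Q = 1, B = b3, M = q[2] - lgt[2] / b3, nu = 1)
            cands <- c(cands, fitGLQuiet(fs, control = control, init = init3))
          }
        }
        # lowest final objective wins, but a converged candidate within a
        # 0.1% relative margin of the best is preferred over an unconverged
        # one (the starts typically meet in the same basin)
        etas <- vapply(cands, function(f) f@report@etaFinal, numeric(1))
        conv <- vapply(cands, function(f) f@report@converged, logical(1))
        close <- etas <= min(etas) * (1 + 1e-3) + 1e-12
        pick <- if (any(conv & close)) which(conv & close) else which(close)
        fit <- cands[[pick[which.min(etas[pick])]]]
        if (!fit@report@converged)
          warning(sprintf(
            "feature '%s': curve fit did not converge within the iteration budget", nm))
        p <- fittedParams(fit)
        rec$params <- list(Q = p@Q, B = p@B, M = p@M, nu = p@nu,
                           etaInit = fit@report@etaInit,
                           etaFinal = fit@report@etaFinal)
        rec
      })
  })

  new("ScalerModel", method = method, features = features,
      featureNames = colnames(x), nTrain = nrow(x),
      version = MODEL_FORMAT_VERSION)
}

#' Transform a matrix with a fitted scaling model
#'
#' Applies the per-feature maps stored in `model`. The generalized logistic
#' map sends every finite value — however far outside the training range —
#' strictly into (0, 1). Min-max maps the training range onto \[0, 1\] and
#' deliberately lets unseen out-of-range values fall outside it (no
#' clipping), and z-score is the stored affine map; both reproduce the
#' documented sensitivity of those baselines. Fallback features yield the
#' constant 0.5 (gl) or 0 (minmax/zscore).
#'
#' @param model a [ScalerModel-class].
#' @param x matrix or data.frame with the same number and order of features
#'   the model was fitted on.
#' @return A numeric matrix of the same shape as `x`.
#' @export
applyScaler <- function(model, x) {
  if (!is(model, "ScalerModel")) stop("'model' must be a ScalerModel")
  validObject(model)
  x <- asFeatureMatrix(x)
  if (ncol(x) != length(model@features))
    stop(sprintf("feature-count mismatch: model has %d features, data has %d",
                 length(model@features), ncol(x)))
  out <- x
  for (j in seq_len(ncol(x))) {
    rec <- model@features[[j]]
    v <- x[, j]
    out[, j] <- if (isTRUE(rec$fallback)) {
      if (model@method == "gl") rep(0.5, length(v)) else rep(0, length(v))
    } else switch(model@method,
      none = v,
      minmax = (v - rec$params$xMin) / (rec$params$xMax - rec$params$xMin),
      zscore = (v - rec$params$mean) / rec$params$sd,
      gl = glEval(glParams(rec$params$Q, rec$params$B,
                           rec$params$M, rec$params$nu), v))
  }
  colnames(out) <- model@featureNames
  out
}

#' Persist a scaling model as JSON
#'
#' Writes the model with 17 significant digits per number, so a write/read
#' round trip reproduces every parameter bit-for-bit.
#'
#' @param model a [ScalerModel-class].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @seealso [readScalerModel()]
#' @export
writeScalerModel <- function(model, path) {
  if (!is(model, "ScalerModel")) stop("'model' must be a ScalerModel")
  validObject(model)
  doc <- list(format_version = model@version,
              method = model@method,
              n_train = model@nTrain,
              features = lapply(model@features, function(f)
                list(name = f$name, fallback = f$fallback, params = f$params)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a scaling model from JSON
#'
#' Validates the format version, the presence and shape of every per-feature
#' record, and the parameter invariants (positive Q, B, nu for the
#' generalized logistic map; positive sd for z-score) before returning.
#'
#' @param path file written by [writeScalerModel()].
#' @return A [ScalerModel-class].
#' @export
readScalerModel <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed model file: ", conditionMessage(e)))
  for (field in c("format_version", "method", "n_train", "features"))
    if (is.null(doc[[field]]))
      stop(sprintf("malformed model file: missing '%s'", field))
  if (!identical(doc$format_version, MODEL_FORMAT_VERSION))
    stop(sprintf("incompatible model format version '%s' (expected '%s')",
                 doc$format_version, MODEL_FORMAT_VERSION))
  if (!doc$method %in% c("gl", "minmax", "zscore", "none"))
    stop(sprintf("malformed model file: unknown method '%s'", doc$method))

  features <- lapply(doc$features, function(f) {
    if (is.null(f$name) || is.null(f$fallback))
      stop("malformed model file: incomplete per-feature record")
    params <- lapply(f$params, as.numeric)
    if (!isTRUE(f$fallback)) {
      need <- switch(doc$method, gl = c("Q", "B", "M", "nu"),
                     minmax = c("xMin", "xMax"), zscore = c("mean", "sd"),
                     none = character())
      if (!all(need %in% names(params)))
        stop(sprintf("malformed model file: feature '%s' is missing parameters",
                     f$name))
      if (doc$method == "gl" &&
          (params$Q <= 0 || params$B <= 0 || params$nu <= 0))
        stop(sprintf("invalid model: feature '%s' violates Q, B, nu > 0",
                     f$name))
      if (doc$method == "zscore" && params$sd <= 0)
        stop(sprintf("invalid model: feature '%s' has non-positive sd", f$name))
      if (doc$method == "minmax" && params$xMax <= params$xMin)
        stop(sprintf("invalid model: feature '%s' has xMax <= xMin", f$name))
    }
    list(name = f$name, fallback = isTRUE(f$fallback), params = params)
  })

  new("ScalerModel", method = doc$method, features = features,
      featureNames = vapply(features, `[[`, character(1), "name"),
      nTrain = as.integer(doc$n_train), version = doc$format_version)
}
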