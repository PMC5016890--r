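#' @import methods
NULL

#' Parameters of a generalized logistic curve
#'
#' Container for the four parameters of the generalized logistic (Richards)
#' function \deqn{L(x) = \left(1 + Q e^{-B(x - M)}\right)^{-1/\nu},}
#' a strictly increasing map from the real line onto the open interval (0, 1).
#' `Q`, `B` and `nu` must be strictly positive and `M` finite; under these
#' constraints the curve is a valid CDF surrogate.
#'
#' @slot Q positive shape/asymmetry parameter.
#' @slot B positive growth-rate parameter (units: 1 / data units).
#' @slot M real location parameter, the "center" of the curve (data units).
#' @slot nu positive asymmetry exponent.
#'
#' @seealso [glParams()], [glEval()], [glInverse()], [fitGL()]
#' @exportClass GLParams
setClass("GLParams",
  representation(Q = "numeric", B = "numeric", M = "numeric", nu = "numeric"))

setValidity("GLParams", function(object) {
  msgs <- character()
  for (nm in c("Q", "B", "M", "nu")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v))
      msgs <- c(msgs, sprintf("'%s' must be a single finite number", nm))
  }
  if (length(msgs) == 0L) {
    if (object@Q <= 0) msgs <- c(msgs, "'Q' must be > 0")
    if (object@B <= 0) msgs <- c(msgs, "'B' must be > 0")
    if (object@nu <= 0) msgs <- c(msgs, "'nu' must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GLParams object
#'
#' @param Q,B,M,nu curve parameters; see [GLParams-class].
#' @return A validated [GLParams-class] object.
#' @examples
#' p <- glParams(Q = 1, B = log(9), M = 1, nu = 1)
#' glEval(p, 0)   # 0.1
#' @export
glParams <- function(Q, B, M, nu) {
  new("GLParams", Q = as.numeric(Q), B = as.numeric(B),
      M = as.numeric(M), nu = as.numeric(nu))
}

#' @describeIn GLParams-class shape parameter Q
#' @param object a `GLParams` object.
#' @export
glQ <- function(object) object@Q

#' @describeIn GLParams-class growth rate B
#' @export
glB <- function(object) object@B

#' @describeIn GLParams-class location M
#' @export
glM <- function(object) object@M

#' @describeIn GLParams-class asymmetry exponent nu
#' @export
glNu <- function(object) object@nu

setMethod("show", "GLParams", function(object) {
  cat("GLParams: L(x) = (1 + Q exp(-B (x - M)))^(-1/nu)\n")
  cat(sprintf("  Q = %.6g, B = %.6g, M = %.6g, nu = %.6g\n",
              object@Q, object@B, object@M, object@nu))
})

#' One variable's observed values with cached order statistics
#'
#' Holds the finite observed values of a single variable together with its
#' sample size, minimum, median (mean of the two central order statistics for
#' even n) and maximum. These order statistics anchor the initialization of
#' the generalized logistic fit.
#'
#' @slot values numeric vector of finite observations (length >= 1).
#' @slot n number of observations.
#' @slot xMin,xMed,xMax sample minimum, median and maximum.
#'
#' @seealso [featureSample()], [ecdfTable()], [fitGL()]
#' @exportClass FeatureSample
setClass("FeatureSample",
  representation(values = "numeric", n = "integer",
                 xMin = "numeric", xMed = "numeric", xMax = "numeric"))

setValidity("FeatureSample", function(object) {
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "need at least one observation")
  if (length(object@values) != object@n)
    msgs <- c(msgs, "'n' must equal length(values)")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "all values must be finite")
  if (length(msgs) == 0L &&
      !(object@xMin <= object@xMed && object@xMed <= object@xMax))
    msgs <- c(msgs, "order statistics must satisfy xMin <= xMed <= xMax")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureSample from raw values
#'
#' @param values numeric vector of finite observations.
#' @return A [FeatureSample-class] object with cached order statistics.
#' @examples
#' featureSample(c(3, 1, 2))
#' @export
featureSample <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("'values' must contain at least one observation")
  if (any(!is.finite(values)))
    stop("'values' must be finite (no NA/NaN/Inf)")
  new("FeatureSample", values = values, n = length(values),
      xMin = min(values), xMed = stats::median(values), xMax = max(values))
}

setMethod("show", "FeatureSample", function(object) {
  cat(sprintf("FeatureSample: n = %d, min/med/max = %.6g / %.6g / %.6g\n",
              object@n, object@xMin, object@xMed, object@xMax))
})

#' @describeIn FeatureSample-class observed values
#' @param object a `FeatureSample` object.
#' @export
sampleValues <- function(object) object@values

#' Empirical CDF evaluated at the sample points
#'
#' Step-function table of the empirical cumulative distribution function
#' P(v) = (1/n) * #\{x_i <= v\}: the sorted distinct sample values and, for
#' each, the fraction of observations less than or equal to it. Heights are
#' multiples of 1/n, non-decreasing, and reach exactly 1 at the sample
#' maximum.
#'
#' @slot points sorted distinct sample values.
#' @slot heights ECDF value at each point, in (0, 1].
#' @slot n sample size the heights are scaled by.
#'
#' @seealso [ecdfTable()]
#' @exportClass ECDFTable
setClass("ECDFTable",
  representation(points = "numeric", heights = "numeric", n = "integer"))

setValidity("ECDFTable", function(object) {
  msgs <- character()
  if (length(object@points) != length(object@heights))
    msgs <- c(msgs, "'points' and 'heights' must have equal length")
  if (is.unsorted(object@points, strictly = TRUE))
    msgs <- c(msgs, "'points' must be strictly increasing")
  if (is.unsorted(object@heights))
    msgs <- c(msgs, "'heights' must be non-decreasing")
  if (length(object@heights) &&
      abs(object@heights[length(object@heights)] - 1) > 1e-12)
    msgs <- c(msgs, "height at the maximum must equal 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ECDFTable", function(object) {
  cat(sprintf("ECDFTable: %d distinct points from a sample of n = %d\n",
              length(object@points), object@n))
})

#' Diagnostics from one generalized logistic fit
#'
#' @slot etaInit sum-of-squares objective at the initialization.
#' @slot etaFinal objective at the returned parameters (never above etaInit).
#' @slot iterations number of objective evaluations used by the optimizer.
#' @slot converged whether a convergence tolerance was met within budget.
#' @slot gradNorm Euclidean norm of the objective gradient at the solution.
#'
#' @seealso [fitGL()]
#' @exportClass GLFitReport
setClass("GLFitReport",
  representation(etaInit = "numeric", etaFinal = "numeric",
                 iterations = "integer", converged = "logical",
                 gradNorm = "numeric"))

setValidity("GLFitReport", function(object) {
  msgs <- character()
  if (object@etaFinal < 0) msgs <- c(msgs, "etaFinal must be >= 0")
  if (object@etaFinal > object@etaInit + 1e-12)
    msgs <- c(msgs, "etaFinal must not exceed etaInit")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GLFitReport", function(object) {
  cat(sprintf(
    "GLFitReport: eta %.6g -> %.6g in %d evaluations (converged: %s, |grad| = %.3g)\n",
    object@etaInit, object@etaFinal, object@iterations,
    object@converged, object@gradNorm))
})

#' A fitted generalized logistic curve with its fit report
#'
#' @slot params the fitted [GLParams-class].
#' @slot report a [GLFitReport-class] with objective and convergence
#'   diagnostics.
#' @seealso [fitGL()]
#' @exportClass GLFit
setClass("GLFit",
  representation(params = "GLParams", report = "GLFitReport"))

#' @describeIn GLFit-class extract the fitted parameters
#' @param object a `GLFit` object.
#' @export
fittedParams <- function(object) object@params

#' @describeIn GLFit-class extract the fit report
#' @export
fitReport <- function(object) object@report

setMethod("show", "GLFit", function(object) {
  show(object@params)
  show(object@report)
})

#' A fitted per-feature scaling model
#'
#' One record per training feature, order preserved. For method `"gl"` a
#' record holds fitted [GLParams-class]; for `"minmax"` the training minimum
#' and maximum; for `"zscore"` the training mean and (n-1 denominator)
#' standard deviation; `"none"` stores nothing. Features that cannot be
#' fitted (constant, or too few distinct values for the curve fit) are
#' flagged as fallbacks and transform to a constant.
#'
#' @slot method one of `"gl"`, `"minmax"`, `"zscore"`, `"none"`.
#' @slot features list of per-feature records `list(name, fallback, params)`.
#' @slot featureNames character vector of feature names.
#' @slot nTrain number of training samples the model was fitted on.
#' @slot version model format version string.
#'
#' @seealso [fitScaler()], [applyScaler()], [writeScalerModel()]
#' @exportClass ScalerModel
setClass("ScalerModel",
  representation(method = "character", features = "list",
                 featureNames = "character", nTrain = "integer",
                 version = "character"))

setValidity("ScalerModel", function(object) {
  msgs <- character()
  if (!object@method %in% c("gl", "minmax", "zscore", "none"))
    msgs <- c(msgs, "unknown scaling method")
  if (length(object@features) != length(object@featureNames))
    msgs <- c(msgs, "one record per feature required")
  ok <- vapply(object@features, function(f)
    is.list(f) && all(c("name", "fallback") %in% names(f)), logical(1))
  if (!all(ok)) msgs <- c(msgs, "malformed per-feature record")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ScalerModel", function(object) {
  nf <- length(object@features)
  nfb <- sum(vapply(object@features, function(f) isTRUE(f$fallback), logical(1)))
  cat(sprintf("ScalerModel (method '%s'): %d features (%d fallback), fitted on n = %d\n",
              object@method, nf, nfb, object@nTrain))
})

#' @describeIn ScalerModel-class the scaling method tag
#' @param object a `ScalerModel` object.
#' @export
scalerMethod <- function(object) object@method

#' @describeIn ScalerModel-class number of features in the model
#' @export
nFeatures <- function(object) length(object@features)

#' @describeIn ScalerModel-class per-feature record (name, fallback flag,
#'   parameters)
#' @param i feature index.
#' @export
featureRecord <- function(object, i) object@features[[i]]

#' Cross-validation result for one scaler/classifier pair
#'
#' @slot scaler scaling method evaluated.
#' @slot classifier classifier evaluated (`"logistic"` or `"svm"`).
#' @slot k number of folds.
#' @slot seed seed used for the fold assignment.
#' @slot foldAUROC,foldAccuracy per-fold test metrics (length k).
#' @slot meanAUROC,meanAccuracy arithmetic means over folds.
#' @slot ciAUROC,ciAccuracy 95% t-interval half-widths over folds.
#'
#' @seealso [runBenchmark()]
#' @exportClass CVResult
setClass("CVResult",
  representation(scaler = "character", classifier = "character",
                 k = "integer", seed = "integer",
                 foldAUROC = "numeric", foldAccuracy = "numeric",
                 meanAUROC = "numeric", meanAccuracy = "numeric",
                 ciAUROC = "numeric", ciAccuracy = "numeric"))

setValidity("CVResult", function(object) {
  msgs <- character()
  if (length(object@foldAUROC) != object@k ||
      length(object@foldAccuracy) != object@k)
    msgs <- c(msgs, "per-fold metric lengths must equal k")
  if (any(object@foldAUROC < 0 | object@foldAUROC > 1) ||
      any(object@foldAccuracy < 0 | object@foldAccuracy > 1))
    msgs <- c(msgs, "AUROC and accuracy must lie in [0, 1]")
  if (abs(object@meanAUROC - mean(object@foldAUROC)) > 1e-12 ||
      abs(object@meanAccuracy - mean(object@foldAccuracy)) > 1e-12)
    msgs <- c(msgs, "means must equal arithmetic means of fold values")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s / %s, %d-fold]: AUROC %.3f +/- %.3f, accuracy %.3f +/- %.3f\n",
              object@scaler, object@classifier, object@k,
              object@meanAUROC, object@ciAUROC,
              object@meanAccuracy, object@ciAccuracy))
})

#' @describeIn CVResult-class flatten to a one-row data.frame of aggregates
#' @param x a `CVResult` object.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @export
as.data.frame.CVResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(scaler = x@scaler, classifier = x@classifier, k = x@k,
             meanAUROC = x@meanAUROC, ciAUROC = x@ciAUROC,
             meanAccuracy = x@meanAccuracy, ciAccuracy = x@ciAccuracy,
             stringsAsFactors = FALSE)
}
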