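# Core numerics for the generalized logistic (GL) CDF surrogate:
# curve evaluation, ECDF construction, least-squares objective with analytic
# gradient, order-statistic parameter initialization, and the fitting loop.

LOG2_10 <- log2(10)

# log(1 + exp(s)), stable for any s
.log1pexp <- function(s) {
  out <- numeric(length(s))
  hi <- s > 33
  out[hi] <- s[hi] + log1p(exp(-s[hi]))
  out[!hi] <- log1p(exp(s[!hi]))
  out
}

.checkParams <- function(params) {
  if (!is(params, "GLParams")) stop("'params' must be a GLParams object")
  validObject(params)
}

#' Evaluate the generalized logistic curve
#'
#' Computes \eqn{L(x) = (1 + Q e^{-B(x-M)})^{-1/\nu}}, a strictly increasing
#' map of the real line onto (0, 1). Evaluation is carried out in log space,
#' so values far below the center (where the exponential would overflow) are
#' handled without loss of monotonicity.
#'
#' @param params a [GLParams-class] object.
#' @param x numeric vector of finite evaluation points.
#' @return Numeric vector of curve values, strictly inside (0, 1).
#' @examples
#' glEval(glParams(1, 1, 0, 1), 0)        # 0.5, the center
#' glEval(glParams(1, log(9), 1, 1), 0)   # 0.1
#' @export
glEval <- function(params, x) {
  .checkParams(params)
  if (any(!is.finite(x))) stop("'x' must be finite")
  s <- log(params@Q) - params@B * (x - params@M)
  out <- exp(-.log1pexp(s) / params@nu)
  # keep the open-interval guarantee at machine precision: far above the
  # center the exact value is closer to 1 than one ulp
  pmax(pmin(out, 1 - .Machine$double.eps / 2), .Machine$double.xmin)
}

#' Invert the generalized logistic curve
#'
#' Solves \eqn{L(x) = u} for x: \eqn{x = M - \log((u^{-\nu} - 1)/Q) / B}.
#' Used for inverse-transform sampling from a known GL CDF.
#'
#' @param params a [GLParams-class] object.
#' @param u numeric vector of probabilities, strictly inside (0, 1).
#' @return Numeric vector with `glEval(params, glInverse(params, u)) == u`
#'   to round-off.
#' @examples
#' glInverse(glParams(1, 1, 3, 1), 0.5)   # 3
#' @export
glInverse <- function(params, u) {
  .checkParams(params)
  if (any(!is.finite(u) | u <= 0 | u >= 1))
    stop("'u' must lie strictly inside (0, 1)")
  # u^(-nu) - 1 computed as expm1 for accuracy near u = 1
  params@M - log(expm1(-params@nu * log(u)) / params@Q) / params@B
}

#' Empirical CDF of a feature sample
#'
#' Builds the step-function table \eqn{\hat P(v) = \frac1n \sum_i 1[x_i \le v]}
#' evaluated at the sorted distinct sample values. Tied observations share a
#' single height equal to the proportion of the sample at or below that value.
#'
#' @param sample a [FeatureSample-class] object.
#' @return An [ECDFTable-class] object.
#' @examples
#' ecdfTable(featureSample(c(5, 5, 5, 9)))  # heights 3/4, 1
#' @export
ecdfTable <- function(sample) {
  if (!is(sample, "FeatureSample")) stop("'sample' must be a FeatureSample")
  pts <- sort(unique(sample@values))
  h <- stats::ecdf(sample@values)(pts)
  new("ECDFTable", points = pts, heights = h, n = sample@n)
}

# ECDF height of every observation (with multiplicity), via its table
.heightsAt <- function(sample, table) {
  if (!is(table, "ECDFTable")) stop("'table' must be an ECDFTable")
  if (table@n != sample@n ||
      !identical(table@points, sort(unique(sample@values))))
    stop("'table' was not derived from 'sample'")
  table@heights[findInterval(sample@values, table@points)]
}

#' Least-squares objective of a GL fit
#'
#' The sum of squared differences between the curve and the empirical CDF
#' over all n sample points (duplicates counted with multiplicity):
#' \eqn{\eta = \sum_i (L(x_i) - \hat P(x_i))^2}.
#'
#' @param params a [GLParams-class] object.
#' @param sample a [FeatureSample-class] object.
#' @param table the [ECDFTable-class] built from `sample`.
#' @return A single non-negative number.
#' @export
glObjective <- function(params, sample, table) {
  h <- .heightsAt(sample, table)
  sum((glEval(params, sample@values) - h)^2)
}

#' Analytic gradient of the GL objective
#'
#' Partial derivatives of [glObjective()] with respect to B, M, Q and nu,
#' summed over the sample. All four terms share the residual factor
#' \eqn{T_1 = 2(\hat P(x_i) - L(x_i))} and the denominator
#' \eqn{T_2 = \nu (Q e^{-B(x_i-M)} + 1)^{1/\nu + 1}}; they are evaluated in
#' log space so large negative \eqn{x_i - M} cannot overflow.
#'
#' @inheritParams glObjective
#' @return Named numeric vector `c(dB, dM, dQ, dnu)`.
#' @export
glGradient <- function(params, sample, table) {
  h <- .heightsAt(sample, table)
  .checkParams(params)
  x <- sample@values
  Q <- params@Q; B <- params@B; M <- params@M; nu <- params@nu
  s <- log(Q) - B * (x - M)     # log of Q e^{-B(x-M)}
  logD <- .log1pexp(s)          # log(1 + Q e^{-B(x-M)})
  L <- exp(-logD / nu)
  T1 <- 2 * (h - L)
  w <- exp(s - (1 / nu + 1) * logD) / nu   # e^{s} / T2
  c(dB  = sum(-T1 * (x - M) * w),
    dM  = sum(T1 * B * w),
    dQ  = sum(T1 * w / Q),
    dnu = sum(-T1 * logD * exp(-logD / nu) / nu^2))
}

# Residual of the Q0 anchor equation: with M0 = x_med, nu0 = log2(1 + Q0)
# and B0 chosen so the minimum maps to 0.1, Q0 must satisfy
#   1 / (1 + Q0 * exp(A(Q0) * r)) = 0.9^(log2(1 + Q0)),
# where A(Q0) = log((1 + Q0)^(log2 10) - 1) - log(Q0) and
# r = (x_max - x_med)/(x_min - x_med) is the (negative) spacing ratio.
# The root makes the initialized curve hit 0.9 at the maximum.
.q0Residual <- function(Q, r) {
  A <- log(expm1(LOG2_10 * log1p(Q))) - log(Q)
  1 / (1 + Q * exp(A * r)) - exp(log2(1 + Q) * log(0.9))
}

.q0ResidualDeriv <- function(Q, r) {
  u <- LOG2_10 * log1p(Q)
  E <- expm1(u)
  A <- log(E) - log(Q)
  Ap <- LOG2_10 / (1 + Q) * exp(u) / E - 1 / Q
  eg <- exp(A * r)
  lhsP <- -eg * (1 + Q * r * Ap) / (1 + Q * eg)^2
  rhs <- exp(log2(1 + Q) * log(0.9))
  lhsP - rhs * log(0.9) / ((1 + Q) * log(2))
}

#' Solve for the initialization shape parameter Q0
#'
#' Finds the positive root of the anchor equation that makes the initialized
#' curve pass through 0.9 at the sample maximum (the 0.5-at-median and
#' 0.1-at-minimum anchors hold identically for every Q0 > 0). The root is
#' located by Newton's method started at Q0 = 1 (exact under symmetric
#' spacing) and safeguarded by bisection inside a sign-change bracket found
#' by a geometric scan of \eqn{[10^{-8}, 10^8]}.
#'
#' The anchor equation is solvable only for spacing ratios
#' \eqn{(x_{max}-x_{med})/(x_{med}-x_{min})} within roughly (0.34, 1.57);
#' outside that band no sign change exists and a convergence error is
#' raised (see the package vignette for the analysis).
#'
#' @param xMin,xMed,xMax strictly increasing sample anchors.
#' @param tol residual tolerance on the anchor equation (default 1e-10).
#' @return The root Q0 > 0 with residual magnitude at most `tol`.
#' @examples
#' initQ0(0, 1, 2)  # symmetric spacing: exactly 1
#' @export
initQ0 <- function(xMin, xMed, xMax, tol = 1e-10) {
  if (!(is.finite(xMin) && is.finite(xMed) && is.finite(xMax)))
    stop("anchors must be finite")
  if (!(xMin < xMed && xMed < xMax))
    stop("anchors must satisfy xMin < xMed < xMax")
  r <- (xMax - xMed) / (xMin - xMed)

  # bracket by geometric scan
  grid <- 10^seq(-8, 8, length.out = 161L)
  fg <- vapply(grid, .q0Residual, numeric(1), r = r)
  exact <- which(fg == 0)
  if (length(exact)) return(grid[exact[1L]])
  sc <- which(diff(sign(fg)) != 0)
  if (!length(sc))
    stop("initQ0 did not converge: no bracketing sign change in [1e-8, 1e8] ",
         sprintf("(spacing ratio %.4g outside the solvable band)",
                 (xMax - xMed) / (xMed - xMin)))
  lo <- grid[sc[1L]]; hi <- grid[sc[1L] + 1L]
  flo <- fg[sc[1L]]

  Q <- if (lo < 1 && 1 < hi) 1 else sqrt(lo * hi)
  fq <- .q0Residual(Q, r)
  for (it in seq_len(200L)) {
    if (abs(fq) <= tol) break
    if (sign(fq) == sign(flo)) { lo <- Q } else { hi <- Q }
    step <- fq / .q0ResidualDeriv(Q, r)
    Qn <- Q - step
    fn <- if (is.finite(Qn) && Qn > lo && Qn < hi) .q0Residual(Qn, r) else NA_real_
    if (!is.finite(fn) || abs(fn) >= abs(fq)) {   # Newton unhelpful: bisect
      Qn <- sqrt(lo * hi)
      fn <- .q0Residual(Qn, r)
    }
    Q <- Qn; fq <- fn
  }
  if (abs(fq) > tol)
    stop("initQ0 did not converge to the requested residual tolerance")
  Q
}

# Initialization from explicit anchors; shared by initParams and fitScaler
# (which substitutes quartiles when the median coincides with an extreme).
# When the anchor equation has no root, Q0 falls back to the symmetric
# default 1 (the 0.5/0.1 anchors are preserved; only the 0.9 anchor moves).
.initFromAnchors <- function(xMin, xMed, xMax) {
  Q0 <- tryCatch(initQ0(xMin, xMed, xMax),
                 error = function(e) {
                   if (grepl("anchors must", conditionMessage(e))) stop(e)
                   1
                 })
  nu0 <- log2(1 + Q0)
  B0 <- (log(expm1(LOG2_10 * log1p(Q0))) - log(Q0)) / (xMed - xMin)
  glParams(Q = Q0, B = B0, M = xMed, nu = nu0)
}

#' Order-statistic initialization of the GL parameters
#'
#' Sets the starting point of the curve fit from three order statistics of
#' the sample: the center M0 is the median; nu0 = log2(1 + Q0) forces the
#' curve through 0.5 at the median; B0 forces it through 0.1 at the minimum;
#' and Q0 solves the anchor equation ([initQ0()]) so it passes through 0.9
#' at the maximum. When that equation has no root (strongly asymmetric
#' spacing) Q0 defaults to 1, keeping the 0.5 and 0.1 anchors exact.
#'
#' @param sample a [FeatureSample-class] with `xMin < xMed < xMax`.
#' @return A [GLParams-class] starting point.
#' @examples
#' p <- initParams(featureSample(c(0, 0.5, 1, 1.5, 2)))
#' glEval(p, c(0, 1, 2))   # 0.1, 0.5, 0.9
#' @export
initParams <- function(sample) {
  if (!is(sample, "FeatureSample")) stop("'sample' must be a FeatureSample")
  if (!(sample@xMin < sample@xMed && sample@xMed < sample@xMax))
    stop("degenerate sample spacing: need xMin < xMed < xMax")
  .initFromAnchors(sample@xMin, sample@xMed, sample@xMax)
}

#' Control settings for the GL curve fit
#'
#' @param maxit iteration budget for the quasi-Newton minimizer.
#' @param gradTol gradient-norm tolerance declaring convergence.
#' @param reltol relative objective-change tolerance passed to the
#'   minimizer (its step-size stopping rule).
#' @return A list of settings for [fitGL()].
#' @export
fitGLControl <- function(maxit = 500L, gradTol = 1e-8, reltol = 1e-10) {
  stopifnot(maxit >= 1, gradTol > 0, reltol > 0)
  list(maxit = as.integer(maxit), gradTol = gradTol, reltol = reltol)
}

#' Fit a generalized logistic curve to a sample's empirical CDF
#'
#' Minimizes the sum of squared deviations between the curve and the ECDF
#' over the four parameters by BFGS with the analytic gradient
#' ([glGradient()]). Positivity of Q, B and nu is enforced by optimizing
#' their logarithms (an unconstrained reparameterization), so no projection
#' or box constraints are needed. The starting point comes from
#' [initParams()] unless an explicit `init` is supplied.
#'
#' @param sample a non-degenerate [FeatureSample-class].
#' @param control settings from [fitGLControl()].
#' @param init optional [GLParams-class] starting point (required when the
#'   sample median coincides with an extreme).
#' @return A [GLFit-class] holding the fitted [GLParams-class] and a
#'   [GLFitReport-class]. If the iteration budget is exhausted the best
#'   iterate is returned with `converged = FALSE` and a warning.
#' @examples
#' set.seed(1)
#' fit <- fitGL(featureSample(rnorm(200)))
#' fittedParams(fit)
#' @export
fitGL <- function(sample, control = fitGLControl(), init = NULL) {
  if (!is(sample, "FeatureSample")) stop("'sample' must be a FeatureSample")
  if (is.null(init)) {
    init <- initParams(sample)   # errors on degenerate spacing
  } else {
    .checkParams(init)
  }
  table <- ecdfTable(sample)
  h <- .heightsAt(sample, table)

  # exp() of an unbounded optimizer step must not overflow to Inf or
  # underflow to 0; clamp the log-parameters to a generous finite range
  fromTheta <- function(th) {
    th <- pmin(pmax(th, -300), 300)
    glParams(Q = exp(th[3L]), B = exp(th[1L]), M = th[2L], nu = exp(th[4L]))
  }
  fn <- function(th) glObjective(fromTheta(th), sample, table)
  gr <- function(th) {
    p <- fromTheta(th)
    g <- glGradient(p, sample, table)
    c(g[["dB"]] * p@B, g[["dM"]], g[["dQ"]] * p@Q, g[["dnu"]] * p@nu)
  }

  th0 <- c(log(init@B), init@M, log(init@Q), log(init@nu))
  etaInit <- fn(th0)
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))

  if (opt$value <= etaInit) {
    pars <- fromTheta(opt$par)
    etaFinal <- opt$value
  } else {               # descent guarantee: never return worse than init
    pars <- init
    etaFinal <- etaInit
  }
  gnorm <- sqrt(sum(glGradient(pars, sample, table)^2))
  converged <- opt$convergence == 0L || gnorm <= control$gradTol
  if (!converged)
    warning("fitGL: iteration budget exhausted before convergence; ",
            "returning best iterate")
  report <- new("GLFitReport", etaInit = etaInit, etaFinal = etaFinal,
                iterations = as.integer(opt$counts[["function"]]),
                converged = converged, gradNorm = gnorm)
  new("GLFit", params = pars, report = report)
}
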