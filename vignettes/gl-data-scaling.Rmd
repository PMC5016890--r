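---
title: "Generalized logistic data scaling: model, fitting, and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized logistic data scaling: model, fitting, and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glscale)
```

## The model

Feature scaling for classification usually means min-max
(\(v' = (v - x_{min})/(x_{max} - x_{min})\)) or the z-score
(\(v' = (v - \bar x)/\sigma_x\)). Both are linear, and both are fragile: one
gross outlier stretches the min-max range so that every ordinary value is
squeezed into a sliver, and inflates the standard deviation similarly. The
alternative implemented here scales each variable through (an estimate of)
its own cumulative distribution function,

\[ v' = P_X(v), \]

the continuous analogue of histogram equalization. An outlier contributes
only \(1/n\) to the empirical CDF, so the map it induces is nearly
indifferent to contamination, and the scaled values are uniform-like on
\((0,1)\) — dense regions are spread apart, which widens class margins
exactly where crowding hurts a classifier.

The empirical CDF itself has no closed form and cannot score unseen values
smoothly, so each variable's ECDF is approximated by a four-parameter
generalized logistic (Richards) curve

\[ L(x) = \bigl(1 + Q e^{-B(x-M)}\bigr)^{-1/\nu},
   \qquad Q, B, \nu > 0, \]

a strictly increasing bijection from the reals onto \((0,1)\): \(M\) locates
the center (data units), \(B\) sets the growth rate (1/data units), and
\(Q\) and \(\nu\) jointly control asymmetry. The fit minimizes

\[ \eta(B, M, Q, \nu) = \sum_{i=1}^n \bigl(L(x_i) - \hat P(x_i)\bigr)^2 \]

over all \(n\) sample points, duplicates with multiplicity, including the
ECDF point at the maximum whose height 1 the curve can approach but never
attain — that residual is simply part of \(\eta\).

## Initialization

The problem is non-convex, so the starting point matters. The default start
is built from three order statistics. Setting \(M_0 = x_{med}\) and asking
\(L(x_{med}) = 0.5\) forces \(\nu_0 = \log_2(1 + Q_0)\); asking
\(L(x_{min}) = 0.1\) then fixes

\[ B_0 = \frac{\ln\bigl((1+Q_0)^{\log_2 10} - 1\bigr) - \ln Q_0}{x_{med} - x_{min}}, \]

and asking \(L(x_{max}) = 0.9\) leaves a single scalar root-finding problem
for \(Q_0\), solved by Newton's method started at \(Q_0 = 1\) (exact under
symmetric spacing) with a bisection safeguard inside a sign-change bracket
located by a geometric scan of \([10^{-8}, 10^8]\), to residual
\(10^{-10}\). Two of the three anchors are in fact algebraic identities: for
*every* \(Q_0 > 0\) the construction gives \(L(x_{med}) = 0.5\) and
\(L(x_{min}) = 0.1\) exactly; only the 0.9 anchor depends on the root.

One genuine limitation surfaced while verifying this construction: the
root exists **only** when the spacing ratio
\(\rho = (x_{max}-x_{med})/(x_{med}-x_{min})\) lies in roughly
\((0.34,\ 1.57)\). Outside that band the residual approaches zero only in
the degenerate limit \(Q_0 \to 0\), where the 0.9 anchor converges to
\(0.9\,e^{c(\rho)} \ne 0.9\); a sample such as \(\{0, 1, 3\}\) (\(\rho = 2\))
has no solution at all. `initQ0()` raises a convergence error there, and
`initParams()` falls back to the symmetric default \(Q_0 = 1\), which keeps
the 0.5 and 0.1 anchors exact and lets the subsequent optimization absorb
the asymmetry. The anchored identities should therefore be read as holding
on the solvable band, not for arbitrary samples.

## Optimization

\(\eta\) is smooth with cheap analytic partial derivatives (all four share
the residual factor \(T_1 = 2(\hat P(x_i) - L(x_i))\) and the denominator
\(T_2 = \nu(Qe^{-B(x_i-M)}+1)^{1/\nu+1}\)), so the minimizer is BFGS using
that gradient. Positivity of \(Q, B, \nu\) is enforced by optimizing their
logarithms — an unconstrained reparameterization rather than projection —
with the log-parameters clamped to \(\pm 300\) so an aggressive line search
cannot overflow `exp()`. Stopping: relative objective change \(10^{-10}\)
or gradient norm \(10^{-8}\), budget 500 iterations; a fit that exhausts
the budget returns its best iterate with `converged = FALSE` and a warning,
and the returned objective is never above the initial one. Evaluation of
\(L\), \(\eta\) and the gradient is done in log space (`log1p`-based), so
points thousands of scale units below the center neither overflow nor lose
monotonicity; the final curve value is clamped into
\([x_{tiny}, 1 - \varepsilon/2]\) because in double precision the exact
value saturates to 1 within one ulp far above the center.

`fitScaler()` adds a multi-start layer on top of the single-start
`fitGL()`: besides the order-statistic anchors it tries a moment-matched
symmetric logistic (\(B = 1.6/\hat\sigma\), \(M = \bar x\)) and a logistic
logit-matched to the ECDF at the quartiles, keeping the lowest final
\(\eta\) (with a converged candidate preferred over an unconverged one
whenever it lies within a 0.1% relative margin of the best — the starts
usually meet in the same basin and differ only in polishing). The third start exists because of a concrete failure mode:
on zero-inflated variables (median = minimum, common in expression data)
the anchor start descends into a plateau where \(\nu\) diverges and the
curve degenerates to the constant 1; the quartile start, which passes
through the ECDF value of the point mass by construction, lands in the
correct basin. All starts are deterministic, so fitting is reproducible
byte-for-byte.

Degenerate features never raise during `fitScaler()`: constants are
flagged and transform to 0.5 (gl) or 0 (minmax/z-score); when the median
coincides with an extreme the offending anchor is replaced by the 75th/25th
percentile for initialization, and only if still degenerate does the
feature fall back.

## Scaling semantics

Models are fit-on-train only: a `ScalerModel` freezes per-feature
parameters and transforming any matrix consults nothing but those
parameters (verified by a test that mangles other test rows). The GL map
sends every finite input strictly into \((0,1)\); min-max deliberately does
**not** clip out-of-range unseen values and the z-score map is unbounded —
preserving those weaknesses is required for an honest comparison. The
z-score uses the \(n-1\) denominator. Min-max implements
\(v' = (v - x_{min})/(x_{max} - x_{min})\), the mapping onto \([0,1]\) that
the method's stated purpose implies. Models persist as JSON with 17
significant digits, which round-trips IEEE doubles exactly.

## Synthetic data

The generators exist to emulate the two qualitative mechanisms the method
is built around, not any particular real dataset:

* `genContaminated()` appends outliers at `base_max + magnitude × range` to
  a standard-normal base (default scenario: n = 200, one outlier at 100×
  range), the setting in which each outlier moves the ECDF of the original
  points by at most \(n_{out}/(n + n_{out})\).
* `genTwoClass()` places two 2-D clusters against the diagonal boundary
  \(x_1 + x_2 = 0\): the coordinate along the boundary normal is a shifted
  log-normal (log-sd 0.5) whose density piles up toward the boundary, the
  tangential coordinate is standard normal, and the classes are separated
  by a guaranteed gap (default 1). Crowded-but-separable is precisely the
  regime where nonlinear spreading near the boundary pays.
* `genBenchmarkScenario()` combines both stressors: feature 1 inflated
  10^6-fold and 3 rows corrupted at 100× its range (defaults: 60 samples
  per class).
* `sampleFromGL()` draws exactly from a given curve by inverse transform.

All generators run under a named Mersenne-Twister seed and restore the
caller's RNG state; identical seeds give bit-identical data. What these
generators do **not** emulate: correlated features, heavy class imbalance,
discrete/ordinal variables, and real measurement noise — so green tests
demonstrate the claimed mechanisms, not performance on any particular
clinical dataset.

## Benchmark harness

`runBenchmark()` reproduces the evaluation protocol: stratified k-fold
cross-validation (default k = 5; per-fold class counts within one of
proportionality; one shared fold assignment per run so scalers face
identical splits), scalers fitted per training fold only, and two
classifiers — ridge-penalized logistic regression (penalty \(10^{-3}\),
needed because well-scaled small-sample data are routinely separable) and
a linear SVM with unit cost; neither rescales internally, since scaling is
the treatment under study. AUROC is the Mann–Whitney statistic with
midrank ties. Accuracy uses a threshold chosen on the *training* scores:
scan the distinct scores (plus \(-\infty\)) under "positive iff score ≥
threshold" and take the minimum score achieving maximal training accuracy,
with \(-\infty\) chosen only when strictly better. Fold metrics aggregate
as means with 95% Student-t half-widths
(\(t_{0.975,k-1}\,\mathrm{SD}/\sqrt{k}\)), the defensible default when
only per-fold values exist.

## Problem sizes and numerical checks

The shipped tests run at deliberately modest sizes — gradient checks on
100 randomized 10–60-point samples against central finite differences
(relative error \(10^{-5}\), step \(10^{-6}(1+|\theta|)\)), parameter
recovery at n = 2000 against the generating curve and n = 5000 against the
normal CDF (sup-distance ≤ 0.02), uniformization at n = 5000
(KS ≤ 0.05), and the scaler comparison over 20 seeded replicates of the
120-sample stress scenario (GL is required to match or beat min-max mean
AUROC in at least 16). Each stochastic check fixes its seed, so results
are reproducible, and each independent oracle (bisection for the root,
finite differences for the gradient, all-pairs counts for AUROC,
exhaustive scans for the threshold) shares no code with the implementation
it checks.

## Known limitations

* The anchored initialization identities hold only on the solvable
  asymmetry band described above; elsewhere the fit still works but starts
  from the symmetric default.
* The fit is a local minimizer; multi-start reduces but does not eliminate
  dependence on initialization.
* Each variable is scaled independently; no joint/multivariate CDF
  modelling, and no \([-1,1]\) min-max variant or rank-based competitor is
  provided.
* Values exactly at 0 or 1 are unreachable by design; downstream code
  relying on attaining the endpoints should rescale.
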