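# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive re-derivation (brute force, enumeration, bisection,
# finite differences) that shares no code with the package internals.

# ECDF by the literal double-loop indicator count
bruteEcdf <- function(values, v) {
  vapply(v, function(q) sum(values <= q) / length(values), numeric(1))
}

# GL curve straight from its printed form (no log-space tricks)
naiveGL <- function(Q, B, M, nu, x) 1 / (1 + Q * exp(-B * (x - M)))^(1 / nu)

# Residual of the Q0 anchor equation, written directly from its closed form
q0AnchorResidual <- function(Q, xMin, xMed, xMax) {
  r <- (xMax - xMed) / (xMin - xMed)
  A <- log((1 + Q)^log2(10) - 1) - log(Q)
  1 / (1 + Q * exp(A * r)) - 0.9^log2(1 + Q)
}

# Fine-grid scan + plain bisection for the Q0 root; independent of initQ0
bisectQ0 <- function(xMin, xMed, xMax, gridPoints = 4001L) {
  g <- 10^seq(-6, 6, length.out = gridPoints)
  f <- vapply(g, q0AnchorResidual, numeric(1),
              xMin = xMin, xMed = xMed, xMax = xMax)
  sc <- which(diff(sign(f)) != 0)
  if (!length(sc)) stop("oracle: no sign change")
  lo <- g[sc[1]]; hi <- g[sc[1] + 1]
  flo <- f[sc[1]]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- q0AnchorResidual(mid, xMin, xMed, xMax)
    if (sign(fm) == sign(flo)) lo <- mid else hi <- mid
    if (hi - lo < 1e-14 * (1 + hi)) break
  }
  (lo + hi) / 2
}

# Central finite differences of the fit objective in (B, M, Q, nu) order
fdGradient <- function(params, sample, table) {
  th <- c(glB(params), glM(params), glQ(params), glNu(params))
  vapply(1:4, function(k) {
    h <- 1e-6 * (1 + abs(th[k]))
    tp <- th; tm <- th
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    mk <- function(t) glParams(Q = t[3], B = t[1], M = t[2], nu = t[4])
    (glObjective(mk(tp), sample, table) -
       glObjective(mk(tm), sample, table)) / (2 * h)
  }, numeric(1))
}

# AUROC by the all-pairs count, ties worth one half
bruteAuroc <- function(scores, labels) {
  y <- as.integer(labels == sort(unique(labels))[2])
  sp <- scores[y == 1]; sn <- scores[y == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Exhaustive threshold scan under "positive iff score >= t", candidates the
# distinct scores plus -Inf, ties resolved to the minimum finite score
bruteThreshold <- function(scores, labels) {
  y <- as.integer(labels == sort(unique(labels))[2])
  cand <- sort(unique(scores))
  acc <- vapply(cand, function(t) mean((scores >= t) == y), numeric(1))
  if (mean(y == 1) > max(acc)) return(-Inf)
  cand[which.max(acc)]
}

# All multisets of a given size from an alphabet (for ECDF enumeration)
allMultisets <- function(alphabet, size) {
  if (size == 1L) return(as.list(alphabet))
  out <- list()
  rec <- function(prefix, startIdx, left) {
    if (left == 0L) { out[[length(out) + 1L]] <<- prefix; return() }
    for (i in startIdx:length(alphabet))
      rec(c(prefix, alphabet[i]), i, left - 1L)
  }
  rec(numeric(0), 1L, size)
  out
}

# Sup-distance between two curves over an interval
supDist <- function(f, g, lo, hi, m = 4000L) {
  xs <- seq(lo, hi, length.out = m)
  max(abs(f(xs) - g(xs)))
}
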