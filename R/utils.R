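# Internal helpers shared across modules.

# Run code under a fixed, named RNG (Mersenne-Twister) without disturbing
# the caller's random state. All stochastic entry points route through this
# so a given seed is portable across sessions and releases.
withSeed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Coerce a feature matrix argument: numeric matrix or data.frame, finite,
# at least one column. Returns a plain numeric matrix with column names.
asFeatureMatrix <- function(x, what = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix or data.frame", what))
  if (ncol(x) < 1L || nrow(x) < 1L)
    stop(sprintf("'%s' must have at least one row and one column", what))
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values; missing values are not supported", what))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

# Coerce labels to 0/1 integer with 1 = positive class.
asBinaryLabels <- function(labels, n = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L)
    stop("'labels' must contain exactly two classes")
  y <- as.integer(labels == u[2L])
  if (!is.null(n) && length(y) != n)
    stop("'labels' length must match the number of rows")
  y
}
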