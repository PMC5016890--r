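# Cross-validation benchmark harness: stratified folds, AUROC via the
# Mann-Whitney statistic, the minimum-threshold accuracy rule, and the
# scaler x classifier comparison loop. Scalers are fitted on the training
# rows of each fold only; test rows are transformed through the frozen model.

#' Stratified k-fold assignment
#'
#' Partitions sample indices into k folds so that each fold's class counts
#' differ from exact proportionality by less than one (shuffled round-robin
#' within class).
#'
#' @param labels two-class label vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the within-class shuffle.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  y <- asBinaryLabels(labels)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2")
  if (any(table(y) < k))
    stop("each class must have at least k members")
  fold <- integer(length(y))
  withSeed(seed, for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counted one half, computed from midranks.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels two-class labels aligned with `scores`.
#' @return AUROC in \[0, 1\].
#' @examples
#' aurocScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
aurocScore <- function(scores, labels) {
  y <- asBinaryLabels(labels, n = length(scores))
  if (any(!is.finite(scores))) stop("'scores' must be finite")
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  r <- rank(scores)   # midranks handle ties as 1/2
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Accuracy-maximizing score threshold with the minimum-threshold tie rule
#'
#' Scans the distinct training scores (plus -Inf, the all-positive rule)
#' under the decision "predict positive iff score >= threshold" and returns
#' the threshold attaining maximal training accuracy. Ties are broken by the
#' minimum *score*: -Inf is returned only when it is strictly better than
#' every finite candidate.
#'
#' @param scores training-fold classifier scores.
#' @param labels training-fold labels.
#' @return The selected threshold.
#' @examples
#' selectThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))  # 0.8
#' @export
selectThreshold <- function(scores, labels) {
  y <- asBinaryLabels(labels, n = length(scores))
  if (any(!is.finite(scores))) stop("'scores' must be finite")
  cand <- sort(unique(scores))
  acc <- vapply(cand, function(t) mean((scores >= t) == y), numeric(1))
  best <- max(acc)
  accAll <- mean(y == 1L)   # threshold -Inf: predict everything positive
  if (accAll > best) return(-Inf)
  cand[which(acc == best)[1L]]
}

# Train one classifier on (x, y) and return a scoring closure.
# Logistic regression uses a light ridge penalty (separable data are the
# norm after good scaling); the max-margin classifier is a linear SVM with
# unit cost. Neither rescales internally: scaling quality is the object of
# study. SVM decision values are oriented on the training fold so that
# higher = positive class.
.trainClassifier <- function(classifier, x, y) {
  if (classifier == "logistic") {
    fit <- glmnet::glmnet(x, factor(y, levels = c(0L, 1L)),
                          family = "binomial", alpha = 0, lambda = 1e-3,
                          standardize = FALSE)
    function(newx) as.numeric(stats::predict(fit, newx, type = "link"))
  } else if (classifier == "svm") {
    fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
                      cost = 1, scale = FALSE)
    score <- function(newx) {
      p <- stats::predict(fit, newx, decision.values = TRUE)
      as.numeric(attr(p, "decision.values"))
    }
    flip <- {
      s <- score(x)
      mean(s[y == 1L]) < mean(s[y == 0L])
    }
    if (flip) function(newx) -score(newx) else score
  } else stop(sprintf("unknown classifier '%s'", classifier))
}

#' Cross-validated comparison of scaling methods
#'
#' For every scaler/classifier pair: assign stratified folds once (shared
#' across pairs), and per fold fit the scaler on the training rows only,
#' transform training and test rows through it, train the classifier on the
#' scaled training fold, and score the test fold. AUROC comes from the test
#' scores; accuracy uses the threshold selected on the *training* scores by
#' [selectThreshold()]. Fold metrics are aggregated as means with 95%
#' t-interval half-widths.
#'
#' @param x numeric feature matrix (samples x features).
#' @param labels two-class label vector.
#' @param scalers character vector of scaling methods to compare.
#' @param classifiers character vector among `"logistic"`, `"svm"`.
#' @param k number of folds.
#' @param seed integer seed (fold assignment).
#' @param control curve-fit settings from [fitGLControl()].
#' @return A list of [CVResult-class], one per scaler/classifier pair.
#' @examples
#' d <- genTwoClass(20, separation = 5, seed = 3)
#' res <- runBenchmark(d$x, d$labels, scalers = "minmax",
#'                     classifiers = "svm", k = 2, seed = 1)
#' res[[1]]
#' @export
runBenchmark <- function(x, labels,
                         scalers = c("none", "minmax", "zscore", "gl"),
                         classifiers = c("logistic", "svm"),
                         k = 5L, seed = 1L, control = fitGLControl()) {
  x <- asFeatureMatrix(x)
  y <- asBinaryLabels(labels, n = nrow(x))
  scalers <- match.arg(scalers, c("none", "minmax", "zscore", "gl"),
                       several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("logistic", "svm"),
                           several.ok = TRUE)
  k <- as.integer(k)
  fold <- stratifiedKFold(y, k, seed)

  results <- list()
  for (sc in scalers) for (cl in classifiers) {
    au <- numeric(k)
    ac <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        stop("degenerate fold: a fold is missing a class")
      model <- suppressWarnings(fitScaler(x[tr, , drop = FALSE], sc, control))
      xtr <- applyScaler(model, x[tr, , drop = FALSE])
      xte <- applyScaler(model, x[!tr, , drop = FALSE])
      scorer <- .trainClassifier(cl, xtr, y[tr])
      sTr <- scorer(xtr)
      sTe <- scorer(xte)
      au[f] <- aurocScore(sTe, y[!tr])
      thr <- selectThreshold(sTr, y[tr])
      ac[f] <- mean((sTe >= thr) == y[!tr])
    }
    hw <- function(v) if (k > 1L)
      stats::qt(0.975, k - 1L) * stats::sd(v) / sqrt(k) else NA_real_
    results[[paste(sc, cl, sep = ".")]] <-
      new("CVResult", scaler = sc, classifier = cl, k = k,
          seed = as.integer(seed), foldAUROC = au, foldAccuracy = ac,
          meanAUROC = mean(au), meanAccuracy = mean(ac),
          ciAUROC = hw(au), ciAccuracy = hw(ac))
  }
  results
}

#' Flatten benchmark results to a data.frame
#'
#' @param results list of [CVResult-class] from [runBenchmark()].
#' @param perFold if `TRUE`, one row per fold; otherwise one aggregate row
#'   per scaler/classifier pair.
#' @return A data.frame.
#' @export
benchmarkTable <- function(results, perFold = FALSE) {
  if (!perFold)
    return(do.call(rbind, lapply(results, as.data.frame.CVResult)))
  do.call(rbind, lapply(results, function(r)
    data.frame(scaler = r@scaler, classifier = r@classifier,
               fold = seq_len(r@k), auroc = r@foldAUROC,
               accuracy = r@foldAccuracy, stringsAsFactors = FALSE)))
}
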