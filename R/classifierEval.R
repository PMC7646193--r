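#' Stratified fold assignment
#'
#' Partitions sample indices into `nFolds` folds so that each fold
#' carries (as nearly as possible) the global positive/negative ratio.
#' Within each class, indices are shuffled and dealt round-robin.
#'
#' @param labels 0/1 vector.
#' @param nFolds number of folds, default 5.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..nFolds) parallel to labels.
#' @export
stratifiedFolds <- function(labels, nFolds = 5L, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0))
    stop("both classes must be present", call. = FALSE)
  if (nFolds > min(counts))
    stop("nFolds exceeds the smaller class count", call. = FALSE)
  fold <- integer(length(labels))
  .withSeed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}

#' Threshold and ranking metrics for binary scores
#'
#' Computes the confusion-matrix metrics at a fixed threshold plus the
#' two ranking areas: accuracy, sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), Matthews correlation coefficient
#' (0 when its denominator vanishes), AUC by trapezoidal ROC
#' integration (tied scores handled at midpoint, equivalent to the
#' Mann-Whitney statistic), and AUPR by precision-recall step
#' integration.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in [0, 1] (higher = more positive).
#' @param threshold score cut for the confusion matrix, default 0.5.
#' @return named numeric vector: acc, sen, spec, prec, mcc, auc, aupr.
#' @examples
#' binaryMetrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1))
#' @export
binaryMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L)
    stop("AUC/AUPR undefined with a single class", call. = FALSE)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(acc = (tp + tn) / length(labels),
    sen = tp / (tp + fn),
    spec = tn / (tn + fp),
    prec = if (tp + fp > 0) tp / (tp + fp) else 0,
    mcc = if (mccDen > 0) (tp * tn - fp * fn) / mccDen else 0,
    auc = .rocAuc(labels, scores),
    aupr = .prAupr(labels, scores))
}

# ROC points over all score cuts (descending); ties grouped so the
# curve steps diagonally through tied blocks (trapezoid = midpoint).
.rocPoints <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tpCum <- cumsum(lab); fpCum <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(lab); N <- length(lab) - P
  data.frame(fpr = c(0, fpCum[last] / N), tpr = c(0, tpCum[last] / P))
}

.rocAuc <- function(labels, scores) {
  r <- .rocPoints(labels, scores)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

# PR curve with step integration: at each distinct-score cut, precision
# and recall from the cumulative counts; area = sum over recall
# increments of the precision at the new point.
.prPoints <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tpCum <- cumsum(lab)
  nCum <- seq_along(lab)
  last <- !duplicated(grp, fromLast = TRUE)
  P <- sum(lab)
  data.frame(recall = tpCum[last] / P, precision = tpCum[last] / nCum[last])
}

.prAupr <- function(labels, scores) {
  p <- .prPoints(labels, scores)
  sum(diff(c(0, p$recall)) * p$precision)
}

.trainScore <- function(classifier, xTrain, yTrain, xTest, seed) {
  yf <- factor(yTrain, levels = c(0, 1))
  switch(classifier,
    random_forest = {
      fit <- .withSeed(seed, randomForest::randomForest(
        x = xTrain, y = yf, ntree = 100L))
      stats::predict(fit, xTest, type = "prob")[, "1"]
    },
    knn = {
      pr <- .withSeed(seed, class::knn(xTrain, xTest, yf, k = 5L,
                                       prob = TRUE, use.all = TRUE))
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xTrain, yf)
      stats::predict(fit, xTest, type = "raw")[, "1"]
    },
    decision_tree = {
      df <- data.frame(y = yf, xTrain)
      fit <- .withSeed(seed, rpart::rpart(y ~ ., data = df, method = "class"))
      stats::predict(fit, data.frame(xTest), type = "prob")[, "1"]
    },
    stop("unknown classifier '", classifier, "'", call. = FALSE))
}

#' Stratified k-fold cross-validation of a link classifier
#'
#' Trains the chosen classifier on k-1 folds and scores the held-out
#' fold, for each fold in turn; per-fold metrics come from
#' [binaryMetrics()] and the report aggregates mean and sample (n-1)
#' standard deviation. The score used for ranking and AUC is the
#' positive-class probability (for the random forest, the fraction of
#' tree votes); confusion metrics use a 0.5 threshold.
#'
#' @param dataset a [PairDataset-class] object.
#' @param classifier `"random_forest"` (default, 100 trees, Gini
#'   impurity, no depth limit), `"knn"`, `"naive_bayes"` or
#'   `"decision_tree"`.
#' @param nFolds number of folds, default 5.
#' @param seed integer seed driving fold assignment and any classifier
#'   randomness.
#' @return a [CVReport-class] object.
#' @export
crossValidate <- function(dataset,
                          classifier = c("random_forest", "knn",
                                         "naive_bayes", "decision_tree"),
                          nFolds = 5L, seed = 1L) {
  stopifnot(is(dataset, "PairDataset"))
  classifier <- match.arg(classifier)
  y <- dataset@pairs$label
  X <- dataset@features
  fold <- stratifiedFolds(y, nFolds, seed)
  rows <- vector("list", nFolds)
  curves <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    test <- fold == f
    if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L)
      stop("degenerate fold ", f, ": a class is missing", call. = FALSE)
    sc <- .trainScore(classifier, X[!test, , drop = FALSE], y[!test],
                      X[test, , drop = FALSE], seed + f)
    m <- binaryMetrics(y[test], sc)
    rows[[f]] <- data.frame(fold = f, t(m))
    curves[[f]] <- list(roc = .rocPoints(y[test], sc),
                        pr = .prPoints(y[test], sc))
  }
  new("CVReport", folds = do.call(rbind, rows), classifier = classifier,
      config = list(nFolds = nFolds, seed = seed, threshold = 0.5,
                    ntree = if (classifier == "random_forest") 100L else NULL,
                    mode = dataset@mode,
                    behaviorDim = dataset@behaviorDim,
                    attributeDim = dataset@attributeDim),
      curves = curves)
}

#' Aggregate a cross-validation report
#'
#' @param report a [CVReport-class] object.
#' @return data.frame with one row per metric: mean and sample sd over
#'   folds.
#' @export
cvSummary <- function(report) {
  stopifnot(is(report, "CVReport"))
  m <- report@folds[, setdiff(names(report@folds), "fold"), drop = FALSE]
  data.frame(metric = names(m),
             mean = vapply(m, mean, 0),
             sd = vapply(m, stats::sd, 0),
             row.names = NULL)
}

#' @describeIn cvSummary compact display with mean +/- sd per metric
#' @param object a [CVReport-class] object.
#' @export
setMethod("show", "CVReport", function(object) {
  s <- cvSummary(object)
  cat("CVReport (", object@classifier, ", ", nrow(object@folds),
      " folds)\n", sep = "")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
})
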