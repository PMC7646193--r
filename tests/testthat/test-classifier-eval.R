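test_that("stratified folds balance classes and partition the data", {
  y <- rep(c(0, 1), each = 10)
  f <- stratifiedFolds(y, 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == 1), 2)
    expect_equal(sum(f == k & y == 0), 2)
  }
  expect_identical(f, stratifiedFolds(y, 5, seed = 1))
  expect_false(identical(f, stratifiedFolds(y, 5, seed = 2)))
  expect_error(stratifiedFolds(rep(1, 10), 5, seed = 1), "both classes")
  expect_error(stratifiedFolds(c(1, 0, 0, 0, 0, 0), 5, seed = 1),
               "smaller class")
  # near-equal fold positive fractions on unbalanced input
  y2 <- c(rep(1, 23), rep(0, 57))
  f2 <- stratifiedFolds(y2, 5, seed = 3)
  fr <- vapply(1:5, function(k) mean(y2[f2 == k]), 0)
  expect_true(all(abs(fr - mean(y2)) < 1 / 16 + 1e-9))
})

test_that("confusion metrics reproduce direct formula evaluation", {
  # TP=3, FN=2, TN=4, FP=1 at threshold 0.5
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.4, 0.3, 0.2, 0.1)
  m <- binaryMetrics(labels, scores)
  expect_equal(unname(m["acc"]), 0.7)
  expect_equal(unname(m["sen"]), 0.6)
  expect_equal(unname(m["spec"]), 0.8)
  expect_equal(unname(m["prec"]), 0.75)
  expect_equal(unname(m["mcc"]), 10 / sqrt(600))
  # perfect scorer
  p <- binaryMetrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unname(p[c("acc", "sen", "spec", "prec", "mcc",
                          "auc", "aupr")]), rep(1, 7))
  # uninformative constant scorer: midpoint tie handling gives 0.5
  u <- binaryMetrics(rep(c(0, 1), 10), rep(0.5, 20))
  expect_equal(unname(u["auc"]), 0.5)
  expect_error(binaryMetrics(rep(1, 5), runif(5)), "single class")
})

test_that("AUC is invariant under monotone transforms and label swap", {
  set.seed(31)
  labels <- rbinom(200, 1, 0.5)
  scores <- runif(200)
  labels[1:2] <- c(0, 1)
  auc <- unname(binaryMetrics(labels, scores)["auc"])
  for (f in list(function(x) x^3, function(x) plogis(5 * x),
                 function(x) 0.1 + 0.8 * x)) {
    expect_equal(unname(binaryMetrics(labels, f(scores))["auc"]), auc,
                 tolerance = 1e-12)
  }
  swapped <- unname(binaryMetrics(1 - labels, 1 - scores)["auc"])
  expect_equal(swapped, auc, tolerance = 1e-12)
  # agreement with an established ROC implementation
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-10)
})

test_that("cross-validation separates separable data and aggregates honestly", {
  set.seed(5)
  n <- 150
  X <- rbind(matrix(rnorm(n * 4, 2), n, 4), matrix(rnorm(n * 4, -2), n, 4))
  ds <- new("PairDataset",
            pairs = data.frame(mirna = paste0("m", 1:(2 * n)),
                               disease = "d1",
                               label = rep(c(1, 0), each = n)),
            features = X, mode = "behavior_only",
            behaviorDim = 4L, attributeDim = 0L)
  rep <- crossValidate(ds, "random_forest", seed = 2)
  expect_gte(mean(rep@folds$auc), 0.99)
  s <- cvSummary(rep)
  expect_equal(s$mean[s$metric == "auc"], mean(rep@folds$auc))
  expect_equal(s$sd[s$metric == "acc"], sd(rep@folds$acc))
  # metric identity per fold: acc = (sen*P + spec*N) / (P + N)
  fold <- stratifiedFolds(ds@pairs$label, 5, seed = 2)
  for (k in 1:5) {
    P <- sum(ds@pairs$label[fold == k] == 1)
    N <- sum(ds@pairs$label[fold == k] == 0)
    r <- rep@folds[k, ]
    expect_equal(r$acc, (r$sen * P + r$spec * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("permuted labels drive cross-validated AUC to chance", {
  set.seed(17)
  n <- 500
  X <- matrix(rnorm(n * 8), n, 8)
  ds <- new("PairDataset",
            pairs = data.frame(mirna = paste0("m", 1:n), disease = "d1",
                               label = sample(rep(c(0, 1), n / 2))),
            features = X, mode = "behavior_only",
            behaviorDim = 8L, attributeDim = 0L)
  rep <- crossValidate(ds, "random_forest", seed = 9)
  expect_gte(mean(rep@folds$auc), 0.4)
  expect_lte(mean(rep@folds$auc), 0.6)
})

test_that("alternate classifiers run under the same harness", {
  set.seed(6)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3, 1.5), n, 3),
             matrix(rnorm(n * 3, -1.5), n, 3))
  ds <- new("PairDataset",
            pairs = data.frame(mirna = paste0("m", 1:(2 * n)),
                               disease = "d1",
                               label = rep(c(1, 0), each = n)),
            features = X, mode = "behavior_only",
            behaviorDim = 3L, attributeDim = 0L)
  for (clf in c("knn", "naive_bayes", "decision_tree")) {
    rep <- crossValidate(ds, clf, seed = 4)
    expect_equal(nrow(rep@folds), 5)
    expect_gte(mean(rep@folds$auc), 0.85)
    expect_identical(rep@classifier, clf)
  }
})
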