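#' Fit the link classifier on a full training set
#'
#' @param dataset a [PairDataset-class] object (positives + negatives).
#' @param classifier classifier name, default `"random_forest"`.
#' @param seed integer seed.
#' @return a fitted model object of class `midnetModel` (list with the
#'   underlying fit, classifier name and feature layout).
#' @export
fitModel <- function(dataset,
                     classifier = c("random_forest", "knn", "naive_bayes",
                                    "decision_tree"),
                     seed = 1L) {
  stopifnot(is(dataset, "PairDataset"))
  classifier <- match.arg(classifier)
  yf <- factor(dataset@pairs$label, levels = c(0, 1))
  X <- dataset@features
  fit <- switch(classifier,
    random_forest = .withSeed(seed, randomForest::randomForest(
      x = X, y = yf, ntree = 100L)),
    naive_bayes = e1071::naiveBayes(X, yf),
    decision_tree = .withSeed(seed, rpart::rpart(
      y ~ ., data = data.frame(y = yf, X), method = "class")),
    knn = list(x = X, y = yf))  # lazy learner: keep the training set
  structure(list(fit = fit, classifier = classifier, seed = seed,
                 mode = dataset@mode,
                 trainPairs = dataset@pairs[dataset@pairs$label == 1,
                                            c("mirna", "disease")]),
            class = "midnetModel")
}

.scoreModel <- function(model, X) {
  switch(model$classifier,
    random_forest = stats::predict(model$fit, X, type = "prob")[, "1"],
    naive_bayes = stats::predict(model$fit, X, type = "raw")[, "1"],
    decision_tree = stats::predict(model$fit, data.frame(X),
                                   type = "prob")[, "1"],
    knn = {
      pr <- .withSeed(model$seed,
        class::knn(model$fit$x, X, model$fit$y, k = 5L, prob = TRUE,
                   use.all = TRUE))
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    })
}

#' Rank candidate miRNAs for a query disease
#'
#' Builds the (miRNA, disease) feature vector for every candidate,
#' scores it with the fitted classifier and sorts by decreasing score.
#' Ties are broken deterministically by miRNA id. Candidates already
#' known to associate with the disease in the model's training
#' positives are excluded by default, so the list surfaces novel
#' candidates.
#'
#' @param model a fitted model from [fitModel()].
#' @param disease query disease id.
#' @param candidates character vector of candidate miRNA ids; defaults
#'   to every miRNA in the feature sources.
#' @param embedding,attributes feature sources as in [assemblePairs()].
#' @param excludeKnown drop the model's training positives for this
#'   disease, default TRUE.
#' @return data.frame with columns `rank`, `mirna`, `disease`, `score`,
#'   sorted by rank.
#' @export
rankCandidates <- function(model, disease, candidates = NULL,
                           embedding = NULL, attributes = NULL,
                           excludeKnown = TRUE) {
  stopifnot(inherits(model, "midnetModel"), length(disease) == 1L)
  if (is.null(candidates)) {
    src <- if (model$mode == "attribute_only") attributes$mirna
           else {
      W <- embeddingMatrix(embedding)
      W[embedding@nodeKinds == "miRNA", , drop = FALSE]
    }
    candidates <- rownames(src)
  }
  if (excludeKnown) {
    known <- model$trainPairs$mirna[model$trainPairs$disease == disease]
    candidates <- setdiff(candidates, known)
  }
  candidates <- sort(unique(candidates))
  if (!length(candidates))
    stop("no candidates left to rank", call. = FALSE)
  ds <- assemblePairs(
    data.frame(mirna = candidates, disease = disease, label = 0,
               stringsAsFactors = FALSE),
    embedding, attributes, model$mode)
  score <- .scoreModel(model, ds@features)
  ord <- order(-score, candidates)   # ties broken by miRNA id
  data.frame(rank = seq_along(candidates), mirna = candidates[ord],
             disease = disease, score = score[ord],
             stringsAsFactors = FALSE)
}

#' Confirm a top-N prediction list against evidence sets
#'
#' Labels each of the top n ranked miRNAs with the names of the
#' confirmation sources that contain it (joined with ";"), or
#' `"Unconfirmed"`.
#'
#' @param ranked data.frame from [rankCandidates()].
#' @param n list depth, default 50 (capped at the list length).
#' @param confirmationSets named list of character vectors: evidence
#'   source name -> confirmed miRNA ids. May be empty (everything
#'   Unconfirmed, with a warning).
#' @return data.frame of the top n rows with an extra `evidence`
#'   column; attribute `confirmed` holds the count confirmed by at
#'   least one source.
#' @export
confirmTopN <- function(ranked, n = 50L, confirmationSets = list()) {
  stopifnot(is.data.frame(ranked), n >= 1L)
  if (n > nrow(ranked))
    stop("n exceeds the ranked list length", call. = FALSE)
  top <- ranked[seq_len(n), , drop = FALSE]
  if (!length(confirmationSets)) {
    warning("no confirmation sets supplied; all predictions Unconfirmed")
    top$evidence <- "Unconfirmed"
  } else {
    top$evidence <- vapply(top$mirna, function(m) {
      hit <- names(confirmationSets)[vapply(confirmationSets,
                                            function(s) m %in% s, TRUE)]
      if (length(hit)) paste(hit, collapse = ";") else "Unconfirmed"
    }, "")
  }
  attr(top, "confirmed") <- sum(top$evidence != "Unconfirmed")
  top
}
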