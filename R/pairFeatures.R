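#' Reduce an attribute matrix to a fixed width by truncated SVD
#'
#' Projects the rows of an attribute matrix (the miRNA 3-mer table or
#' the disease similarity profile matrix) onto its top right singular
#' vectors: the row scores `U_d Sigma_d`. Deterministic under the
#' package-wide SVD sign convention; when the matrix rank falls short
#' of `dim`, trailing columns are zero.
#'
#' @param X numeric matrix, one row per node (rownames = ids).
#' @param dim target width, 1 <= dim <= ncol(X).
#' @return matrix with `dim` columns and the same rownames.
#' @export
reduceAttributes <- function(X, dim) {
  .svdReduce(X, dim)
}

#' Per-node attribute feature matrices
#'
#' miRNA attributes are the 64-dimensional 3-mer composition reduced to
#' `dim` columns; disease attributes are each disease's row of the
#' semantic similarity matrix reduced (by a separately fitted reducer)
#' to `dim` columns.
#'
#' @param kmers miRNA k-mer table from [kmerTable()].
#' @param simmat disease similarity matrix from
#'   [diseaseSimilarityMatrix()].
#' @param dim per-node attribute width, default 32.
#' @return list with elements `mirna` and `disease`, each a reduced
#'   matrix with rownames = ids.
#' @export
attributeFeatures <- function(kmers, simmat, dim = 32L) {
  list(mirna = .svdReduce(kmers, min(dim, ncol(kmers))),
       disease = .svdReduce(simmat, min(dim, ncol(simmat))))
}

#' Assemble labeled miRNA-disease pair samples
#'
#' Concatenates per-node features into pair vectors laid out as
#' [miRNA behavior | miRNA attribute | disease behavior | disease
#' attribute], restricted to the blocks the mode selects. Under the
#' defaults (behavior 32/node, attribute 32/node, mode `"both"`) each
#' pair is a 128-dimensional vector. The features never see the
#' association labels: behavior comes from a network with no direct
#' miRNA-disease edge and attributes are intrinsic to each node.
#'
#' @param pairs data.frame with columns `mirna`, `disease` and
#'   optionally `label` (default 1).
#' @param embedding a [GraRepEmbedding-class]; required unless mode is
#'   `"attribute_only"`.
#' @param attributes list from [attributeFeatures()]; required unless
#'   mode is `"behavior_only"`.
#' @param mode `"both"` (default), `"behavior_only"` or
#'   `"attribute_only"`.
#' @return a [PairDataset-class] object.
#' @export
assemblePairs <- function(pairs, embedding = NULL, attributes = NULL,
                          mode = c("both", "behavior_only",
                                   "attribute_only")) {
  mode <- match.arg(mode)
  stopifnot(all(c("mirna", "disease") %in% names(pairs)))
  if (is.null(pairs$label)) pairs$label <- 1
  useB <- mode != "attribute_only"
  useA <- mode != "behavior_only"
  if (useB && is.null(embedding))
    stop("mode '", mode, "' needs an embedding", call. = FALSE)
  if (useA && is.null(attributes))
    stop("mode '", mode, "' needs attribute features", call. = FALSE)

  lookupRows <- function(M, ids, what) {
    idx <- match(ids, rownames(M))
    if (anyNA(idx))
      stop("unknown ", what, ": ", ids[which(is.na(idx))[1L]], call. = FALSE)
    M[idx, , drop = FALSE]
  }
  blocks <- list()
  bDim <- 0L; aDim <- 0L
  if (useB) {
    W <- embeddingMatrix(embedding)
    bDim <- ncol(W)
    blocks$mb <- lookupRows(W, pairs$mirna, "miRNA")
  }
  if (useA) {
    aDim <- ncol(attributes$mirna)
    if (ncol(attributes$disease) != aDim)
      stop("miRNA and disease attribute widths must match", call. = FALSE)
    blocks$ma <- lookupRows(attributes$mirna, pairs$mirna, "miRNA")
  }
  if (useB) blocks$db <- lookupRows(embeddingMatrix(embedding),
                                    pairs$disease, "disease")
  if (useA) blocks$da <- lookupRows(attributes$disease, pairs$disease,
                                    "disease")
  X <- do.call(cbind, blocks[c("mb", "ma", "db", "da")[
    c(useB, useA, useB, useA)]])
  dimnames(X) <- NULL
  new("PairDataset",
      pairs = data.frame(mirna = pairs$mirna, disease = pairs$disease,
                         label = pairs$label, stringsAsFactors = FALSE),
      features = X, mode = mode,
      behaviorDim = as.integer(bDim), attributeDim = as.integer(aDim))
}

#' Sample negative miRNA-disease pairs
#'
#' Uniform sample without replacement from the unlabeled part of the
#' miRNA x disease universe (all pairs minus the known positives).
#' Reproducible for a given seed. When fewer unlabeled pairs exist
#' than requested, all of them are returned with a warning.
#'
#' @param positives data.frame with columns `mirna`, `disease`.
#' @param mirnas,diseases candidate id vectors spanning the universe.
#' @param ratio negatives per positive, default 1 (balanced classes).
#' @param seed integer seed.
#' @return data.frame with columns `mirna`, `disease`, `label` (= 0).
#' @export
sampleNegatives <- function(positives, mirnas, diseases, ratio = 1,
                            seed = 1L) {
  stopifnot(nrow(positives) >= 1L, ratio > 0)
  nM <- length(mirnas); nD <- length(diseases)
  pi <- match(positives$mirna, mirnas)
  pj <- match(positives$disease, diseases)
  if (anyNA(pi) || anyNA(pj))
    stop("positive pair outside the given universe", call. = FALSE)
  posIdx <- (pi - 1L) * nD + pj
  universe <- setdiff(seq_len(nM * nD), posIdx)
  n <- round(ratio * nrow(positives))
  if (length(universe) == 0L)
    stop("no unlabeled pairs left to sample negatives from", call. = FALSE)
  if (n > length(universe)) {
    warning("requested ", n, " negatives but only ", length(universe),
            " unlabeled pairs exist; returning all of them")
    n <- length(universe)
  }
  sel <- .withSeed(seed,
    sort(universe[sample.int(length(universe), n)]))
  data.frame(mirna = mirnas[(sel - 1L) %/% nD + 1L],
             disease = diseases[(sel - 1L) %% nD + 1L],
             label = 0, stringsAsFactors = FALSE)
}

#' Load known positive miRNA-disease pairs from a TSV file
#'
#' @param path TSV with two identifier columns (miRNA, disease);
#'   `#`-prefixed header/comment lines allowed.
#' @return data.frame with columns `mirna`, `disease`.
#' @export
loadPositives <- function(path) {
  df <- .readEdgeList(path, "positive pair file")
  names(df) <- c("mirna", "disease")
  df
}

#' Build a labeled training set from positives plus sampled negatives
#'
#' Convenience wrapper: draws 1:1 negatives with [sampleNegatives()],
#' stacks them under the positives (label 1) and assembles feature
#' vectors with [assemblePairs()].
#'
#' @inheritParams sampleNegatives
#' @inheritParams assemblePairs
#' @return a [PairDataset-class] object.
#' @export
buildTrainingSet <- function(positives, mirnas, diseases, embedding,
                             attributes, mode = "both", ratio = 1,
                             seed = 1L) {
  neg <- sampleNegatives(positives, mirnas, diseases, ratio, seed)
  pos <- data.frame(mirna = positives$mirna, disease = positives$disease,
                    label = 1, stringsAsFactors = FALSE)
  assemblePairs(rbind(pos, neg), embedding, attributes, mode)
}

#' @describeIn assemblePairs compact display
#' @param object a [PairDataset-class] object.
#' @export
setMethod("show", "PairDataset", function(object) {
  cat("PairDataset:", nrow(object@pairs), "pairs (",
      sum(object@pairs$label == 1), "positive /",
      sum(object@pairs$label == 0), "negative ),",
      ncol(object@features), "features, mode =", object@mode, "\n")
})
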