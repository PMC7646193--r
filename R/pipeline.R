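#' Run the full prediction pipeline on a synthetic world
#'
#' Convenience front-end wiring the modules together: GraRep embedding
#' of the world's network (behavior features), 3-mer composition and
#' DAG semantic similarity (attribute features), 1:1 negative sampling,
#' pair assembly under the chosen combination mode, and stratified
#' k-fold cross-validation.
#'
#' @param world a [SyntheticWorld-class] object (or any list-like
#'   object with the same slots).
#' @param mode feature combination: `"both"` (default),
#'   `"behavior_only"` or `"attribute_only"`.
#' @param K,d GraRep steps and per-step dimension (defaults 2 and 16:
#'   32 behavior dimensions per node).
#' @param attrDim per-node attribute width, default 32 (clipped to the
#'   available attribute widths; the same width is used for both node
#'   kinds so the pair vector stays symmetric).
#' @param delta semantic decay factor, default 0.5.
#' @param classifier classifier name, default `"random_forest"`.
#' @param nFolds folds, default 5.
#' @param seed integer seed for negative sampling, folds and the
#'   classifier.
#' @return a [CVReport-class] object.
#' @examples
#' \donttest{
#' w <- generateWorld(nMirna = 16, nProtein = 24, nDisease = 12, seed = 3)
#' cvSummary(runPipeline(w, d = 8, attrDim = 8, seed = 3))
#' }
#' @export
runPipeline <- function(world, mode = "both", K = 2L, d = 16L,
                        attrDim = 32L, delta = 0.5,
                        classifier = "random_forest", nFolds = 5L,
                        seed = 1L) {
  feats <- pipelineFeatures(world, K = K, d = d, attrDim = attrDim,
                            delta = delta)
  ds <- buildTrainingSet(world@positives,
                         mirnas = nodeIds(world@network, "miRNA"),
                         diseases = nodeIds(world@network, "disease"),
                         embedding = feats$embedding,
                         attributes = feats$attributes,
                         mode = mode, seed = seed)
  crossValidate(ds, classifier = classifier, nFolds = nFolds, seed = seed)
}

#' Compute the feature sources for a world
#'
#' @inheritParams runPipeline
#' @return list with `embedding` (a [GraRepEmbedding-class]) and
#'   `attributes` (list of reduced miRNA / disease matrices).
#' @export
pipelineFeatures <- function(world, K = 2L, d = 16L, attrDim = 32L,
                             delta = 0.5) {
  emb <- graRepEmbed(world@network, K = K, d = d)
  km <- kmerTable(world@sequences)
  dags <- buildAllDAGs(world@descriptors,
                       diseases = nodeIds(world@network, "disease"),
                       delta = delta)
  ss <- diseaseSimilarityMatrix(dags)
  width <- min(attrDim, ncol(km), ncol(ss))
  attrs <- attributeFeatures(km, ss, dim = width)
  list(embedding = emb, attributes = attrs)
}
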