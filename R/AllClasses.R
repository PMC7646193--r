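#' @import methods
#' @importFrom Matrix Matrix t diag rowSums colSums
NULL

#' Heterogeneous miRNA-protein-disease association network
#'
#' Holds the typed node table and the symmetric binary adjacency matrix
#' of a heterogeneous network whose edges connect miRNAs to proteins and
#' proteins to diseases. By construction the network carries no direct
#' miRNA-disease edge, so embeddings derived from it cannot leak the
#' association labels they are later used to predict.
#'
#' @slot nodes data.frame with columns `id` (character, unique),
#'   `kind` (one of `"miRNA"`, `"protein"`, `"disease"`) and `index`
#'   (1-based row/column in the adjacency). Nodes are blocked miRNAs
#'   first, then proteins, then diseases, each block sorted by id.
#' @slot adjacency sparse symmetric 0/1 Matrix with zero diagonal,
#'   dimnames equal to the node ids.
#'
#' @seealso [loadNetwork()], [networkSummary()], [transitionMatrix()]
#' @export
setClass("HeteroNetwork",
  representation(nodes = "data.frame", adjacency = "Matrix"))

setValidity("HeteroNetwork", function(object) {
  nd <- object@nodes
  S <- object@adjacency
  msg <- character()
  if (!all(c("id", "kind", "index") %in% names(nd)))
    msg <- c(msg, "nodes must have columns id, kind, index")
  else {
    if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
    if (!all(nd$kind %in% c("miRNA", "protein", "disease")))
      msg <- c(msg, "node kind must be miRNA, protein or disease")
    if (!identical(nd$index, seq_len(nrow(nd))))
      msg <- c(msg, "node indices must be 1..N in row order")
    kindOrder <- match(nd$kind, c("miRNA", "protein", "disease"))
    if (is.unsorted(kindOrder))
      msg <- c(msg, "nodes must be blocked miRNA, protein, disease")
    if (nrow(S) != nrow(nd) || ncol(S) != nrow(nd))
      msg <- c(msg, "adjacency dimension must equal node count")
  }
  if (length(msg) == 0L) {
    if (!Matrix::isSymmetric(S))
      msg <- c(msg, "adjacency must be symmetric")
    x <- S@x
    if (length(x) && !all(x %in% c(0, 1)))
      msg <- c(msg, "adjacency must be binary")
    if (any(Matrix::diag(S) != 0))
      msg <- c(msg, "adjacency diagonal must be zero")
    # forbidden edge types: miRNA-miRNA, disease-disease, miRNA-disease,
    # protein-protein is also absent from the two input association types
    ij <- Matrix::which(S != 0, arr.ind = TRUE)
    if (nrow(ij)) {
      k1 <- nd$kind[ij[, 1]]
      k2 <- nd$kind[ij[, 2]]
      okPair <- (k1 == "protein" & k2 != "protein") |
                (k2 == "protein" & k1 != "protein")
      if (!all(okPair))
        msg <- c(msg, "every edge must connect a protein to a miRNA or disease")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GraRep global node representation
#'
#' The concatenated k-step representations `W = [W^1 | ... | W^K]`
#' produced by [graRepEmbed()]. Rows follow the node order of the
#' network the embedding was computed from.
#'
#' @slot W numeric matrix, N x (K*d), rownames = node ids.
#' @slot nodeKinds character vector of node kinds parallel to rows.
#' @slot K integer, maximum transition step.
#' @slot d integer, per-step representation dimension.
#' @slot beta numeric, log shift factor.
#' @export
setClass("GraRepEmbedding",
  representation(W = "matrix", nodeKinds = "character",
                 K = "integer", d = "integer", beta = "numeric"))

setValidity("GraRepEmbedding", function(object) {
  if (ncol(object@W) != object@K * object@d)
    return("W must have K*d columns")
  if (length(object@nodeKinds) != nrow(object@W))
    return("nodeKinds must be parallel to rows of W")
  if (is.null(rownames(object@W)))
    return("W must carry node ids as rownames")
  TRUE
})

#' Disease DAG with decay-factor semantic contributions
#'
#' A disease together with all its ontology ancestors (union over the
#' disease's hierarchical tree numbers), the parent-to-child edges among
#' them, and the semantic contribution of each node to the disease.
#'
#' @slot disease character, the disease term id (the DAG's sink).
#' @slot nodes character vector of term ids: the disease plus ancestors.
#' @slot edges data.frame with columns `parent`, `child` (term ids).
#' @slot contributions named numeric, decay contribution per node;
#'   1 at the disease itself, in (0, 1] elsewhere.
#' @slot delta numeric, semantic contribution (decay) factor in (0, 1].
#' @export
setClass("DiseaseDAG",
  representation(disease = "character", nodes = "character",
                 edges = "data.frame", contributions = "numeric",
                 delta = "numeric"))

setValidity("DiseaseDAG", function(object) {
  msg <- character()
  if (length(object@disease) != 1L)
    msg <- c(msg, "disease must be a single id")
  if (length(object@nodes) && !(object@disease %in% object@nodes))
    msg <- c(msg, "disease must be among the DAG nodes")
  cc <- object@contributions
  if (length(cc)) {
    if (!setequal(names(cc), object@nodes))
      msg <- c(msg, "contributions must cover exactly the DAG nodes")
    if (any(cc <= 0 | cc > 1))
      msg <- c(msg, "contributions must lie in (0, 1]")
    if (abs(cc[[object@disease]] - 1) > 1e-12)
      msg <- c(msg, "contribution of the disease itself must be 1")
  }
  if (object@delta <= 0 || object@delta > 1)
    msg <- c(msg, "delta must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Labeled miRNA-disease pair samples with assembled feature vectors
#'
#' @slot pairs data.frame with columns `mirna`, `disease`, `label`
#'   (1 = known association, 0 = sampled negative).
#' @slot features numeric matrix, one row per pair, laid out as
#'   miRNA behavior | miRNA attribute | disease behavior | disease
#'   attribute, restricted to the blocks the mode selects.
#' @slot mode one of `"attribute_only"`, `"behavior_only"`, `"both"`.
#' @slot behaviorDim,attributeDim integer per-node block widths.
#' @export
setClass("PairDataset",
  representation(pairs = "data.frame", features = "matrix",
                 mode = "character", behaviorDim = "integer",
                 attributeDim = "integer"))

setValidity("PairDataset", function(object) {
  msg <- character()
  if (!all(c("mirna", "disease", "label") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns mirna, disease, label")
  else {
    if (nrow(object@features) != nrow(object@pairs))
      msg <- c(msg, "one feature row per pair required")
    if (anyDuplicated(paste(object@pairs$mirna, object@pairs$disease, sep = "\r")))
      msg <- c(msg, "(mirna, disease) pairs must be unique")
    if (!all(object@pairs$label %in% c(0, 1)))
      msg <- c(msg, "labels must be 0 or 1")
    if (length(object@features) && !all(is.finite(object@features)))
      msg <- c(msg, "feature values must be finite")
  }
  if (!object@mode %in% c("attribute_only", "behavior_only", "both"))
    msg <- c(msg, "unknown mode")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' Per-fold and aggregated classification metrics from
#' [crossValidate()]. Means are arithmetic means over folds; the spread
#' is the sample (n-1) standard deviation.
#'
#' @slot folds data.frame, one row per fold with columns `fold`, `acc`,
#'   `sen`, `spec`, `prec`, `mcc`, `auc`, `aupr`.
#' @slot classifier character, classifier name.
#' @slot config list, snapshot of classifier/CV settings.
#' @slot curves list of per-fold ROC and PR curve point tables.
#' @export
setClass("CVReport",
  representation(folds = "data.frame", classifier = "character",
                 config = "list", curves = "list"))

#' Self-contained synthetic world with a planted association signal
#'
#' Generated by [generateWorld()]: a heterogeneous network, miRNA
#' sequences, disease ontology descriptors and known positive pairs,
#' all consistent with a hidden group structure that links miRNA groups
#' to disease groups through shared protein hubs.
#'
#' @slot network a [HeteroNetwork-class] object.
#' @slot sequences named character vector of RNA sequences.
#' @slot descriptors data.frame with columns `tree_number`, `term_id`.
#' @slot positives data.frame with columns `mirna`, `disease`.
#' @slot truth list: group assignment per miRNA/protein/disease id.
#' @slot signal numeric, planted signal strength in [0, 1].
#' @slot seed integer seed the world was generated from.
#' @export
setClass("SyntheticWorld",
  representation(network = "HeteroNetwork", sequences = "character",
                 descriptors = "data.frame", positives = "data.frame",
                 truth = "list", signal = "numeric", seed = "integer"))
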