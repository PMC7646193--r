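#' Build a disease DAG from hierarchical tree numbers
#'
#' A disease's DAG consists of the disease itself and all its ontology
#' ancestors, with edges from parent headings to child headings. Each
#' tree number is a dotted code ("C04.588.894"); every prefix truncation
#' is the code's parent. The node set is the union, over all of the
#' disease's tree numbers, of the full ancestor chains, with codes
#' mapped to terms and duplicate terms merged.
#'
#' @param disease disease term id (becomes the DAG's most specific
#'   node).
#' @param treeNumbers character vector of dotted hierarchical codes for
#'   this disease; may be empty (an empty DAG: similarity 0 to every
#'   other disease, 1 to itself).
#' @param ontology named character vector mapping every code (and every
#'   prefix of every code) to a term id.
#' @param delta semantic contribution (decay) factor in (0, 1],
#'   default 0.5.
#' @return a [DiseaseDAG-class] with contributions computed.
#' @examples
#' ont <- c(C04 = "NeoplasmsBySite", C04.588 = "LungNeoplasms")
#' dag <- buildDiseaseDAG("LungNeoplasms", "C04.588", ont)
#' semanticValue(dag)
#' @export
buildDiseaseDAG <- function(disease, treeNumbers, ontology, delta = 0.5) {
  treeNumbers <- treeNumbers[nzchar(treeNumbers)]
  if (!length(treeNumbers))
    return(new("DiseaseDAG", disease = disease,
               nodes = disease, edges = data.frame(parent = character(),
                                                   child = character()),
               contributions = c(stats::setNames(1, disease)),
               delta = delta))
  edges <- list()
  nodes <- character()
  lookup <- function(code) {
    if (is.na(match(code, names(ontology))))
      stop("unknown tree number '", code, "'", call. = FALSE)
    unname(ontology[[code]])
  }
  for (tn in treeNumbers) {
    parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    chain <- vapply(seq_along(parts),
                    function(i) paste(parts[seq_len(i)], collapse = "."), "")
    terms <- vapply(chain, lookup, "")
    nodes <- c(nodes, terms)
    if (length(terms) > 1L)
      edges[[length(edges) + 1L]] <-
        data.frame(parent = terms[-length(terms)], child = terms[-1L],
                   stringsAsFactors = FALSE)
  }
  nodes <- unique(c(nodes, disease))
  edges <- if (length(edges)) unique(do.call(rbind, edges))
           else data.frame(parent = character(), child = character())
  # the most specific term of each tree number is the disease itself;
  # rewire terminal terms that differ in name onto the disease id
  tips <- vapply(treeNumbers, function(tn) {
    lookup(tn)
  }, "")
  if (any(tips != disease)) {
    edges$parent[edges$parent %in% tips] <- disease
    edges$child[edges$child %in% tips] <- disease
    nodes <- unique(c(setdiff(nodes, tips), disease))
    edges <- unique(edges[edges$parent != edges$child, , drop = FALSE])
  }
  if (.hasCycle(nodes, edges))
    stop("cyclic hierarchy for disease '", disease, "'", call. = FALSE)
  dag <- new("DiseaseDAG", disease = disease, nodes = nodes, edges = edges,
             contributions = numeric(), delta = delta)
  dag@contributions <- semanticContribution(dag, delta)
  validObject(dag)
  dag
}

.hasCycle <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  active <- nodes
  repeat {
    src <- active[indeg[active] == 0L]
    if (!length(src)) break
    active <- setdiff(active, src)
    drop <- edges$parent %in% src
    tab <- table(edges$child[drop])
    indeg[names(tab)] <- indeg[names(tab)] - as.integer(tab)
    edges <- edges[!drop, , drop = FALSE]
  }
  length(active) > 0L
}

#' Decay-factor semantic contributions of DAG nodes
#'
#' The disease itself contributes 1; every ancestor contributes delta
#' times the maximum contribution among its children within the DAG, so
#' contributions decay geometrically with distance from the disease.
#'
#' @param dag a [DiseaseDAG-class] object.
#' @param delta decay factor in (0, 1]; defaults to the DAG's own.
#' @return named numeric vector over the DAG's nodes, values in (0, 1].
#' @export
semanticContribution <- function(dag, delta = dag@delta) {
  stopifnot(is(dag, "DiseaseDAG"), delta > 0, delta <= 1)
  nodes <- dag@nodes
  cc <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  childrenOf <- split(dag@edges$child, dag@edges$parent)
  rec <- function(d, seen = character()) {
    if (!is.na(cc[[d]])) return(cc[[d]])
    if (d %in% seen) stop("cycle through '", d, "'", call. = FALSE)
    if (d == dag@disease) { cc[[d]] <<- 1; return(1) }
    kids <- childrenOf[[d]]
    if (is.null(kids))
      stop("node '", d, "' has no path to the disease", call. = FALSE)
    v <- delta * max(vapply(kids, rec, 0, seen = c(seen, d)))
    cc[[d]] <<- v
    v
  }
  for (d in nodes) rec(d)
  cc
}

#' Semantic value of a disease
#'
#' The sum of the contributions of the disease and all its ancestors;
#' at least 1 since the disease itself contributes 1.
#'
#' @inheritParams semanticContribution
#' @return a single number >= 1.
#' @export
semanticValue <- function(dag, delta = dag@delta) {
  cc <- if (identical(delta, dag@delta) && length(dag@contributions))
    dag@contributions else semanticContribution(dag, delta)
  sum(cc)
}

#' Semantic similarity between two diseases
#'
#' Shared-ancestor contributions summed from both sides, normalised by
#' the two semantic values:
#' `SS(A, B) = sum_{d in D(A) ^ D(B)} (C_A(d) + C_B(d)) / (C(A) + C(B))`.
#' Symmetric, 1 for identical DAGs, 0 for disjoint node sets.
#'
#' @param dagA,dagB [DiseaseDAG-class] objects built with the same
#'   delta.
#' @return similarity in [0, 1].
#' @export
semanticSimilarity <- function(dagA, dagB) {
  stopifnot(is(dagA, "DiseaseDAG"), is(dagB, "DiseaseDAG"))
  if (!isTRUE(all.equal(dagA@delta, dagB@delta)))
    stop("both DAGs must use the same delta", call. = FALSE)
  if (dagA@disease == dagB@disease &&
      setequal(dagA@nodes, dagB@nodes)) return(1)
  shared <- intersect(dagA@nodes, dagB@nodes)
  if (!length(shared)) return(0)
  num <- sum(dagA@contributions[shared]) + sum(dagB@contributions[shared])
  num / (semanticValue(dagA) + semanticValue(dagB))
}

#' Pairwise disease semantic similarity matrix
#'
#' @param dags named list of [DiseaseDAG-class] objects (names default
#'   to each DAG's disease id).
#' @return symmetric numeric matrix with unit diagonal, dimnames = the
#'   disease ids.
#' @export
diseaseSimilarityMatrix <- function(dags) {
  stopifnot(length(dags) >= 1L)
  ids <- if (!is.null(names(dags))) names(dags)
         else vapply(dags, function(d) d@disease, "")
  n <- length(dags)
  SS <- diag(1, n)
  dimnames(SS) <- list(ids, ids)
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    SS[i, j] <- SS[j, i] <- semanticSimilarity(dags[[i]], dags[[j]])
  }
  SS
}

#' Build DAGs for all diseases in a descriptor table
#'
#' @param descriptors data.frame or TSV path with columns
#'   (tree_number, term_id); `#` comments allowed in files.
#' @param diseases optional character vector restricting / ordering the
#'   diseases; defaults to all term ids in the table, first-appearance
#'   order. Ids absent from the table get empty DAGs.
#' @param delta decay factor, default 0.5.
#' @return named list of [DiseaseDAG-class] objects.
#' @export
buildAllDAGs <- function(descriptors, diseases = NULL, delta = 0.5) {
  if (!is.data.frame(descriptors)) {
    descriptors <- .readEdgeList(descriptors, "descriptor file")
    names(descriptors) <- c("tree_number", "term_id")
  }
  stopifnot(all(c("tree_number", "term_id") %in% names(descriptors)))
  ontology <- stats::setNames(descriptors$term_id, descriptors$tree_number)
  if (anyDuplicated(names(ontology)))
    stop("duplicate tree number in descriptors", call. = FALSE)
  if (is.null(diseases)) diseases <- unique(descriptors$term_id)
  byTerm <- split(descriptors$tree_number, descriptors$term_id)
  dags <- lapply(diseases, function(d)
    buildDiseaseDAG(d, if (d %in% names(byTerm)) byTerm[[d]] else character(),
                    ontology, delta))
  names(dags) <- diseases
  dags
}

#' @describeIn semanticContribution compact display
#' @param object a [DiseaseDAG-class] object.
#' @export
setMethod("show", "DiseaseDAG", function(object) {
  cat("DiseaseDAG '", object@disease, "': ", length(object@nodes),
      " nodes, ", nrow(object@edges), " edges, delta = ", object@delta,
      ", semantic value = ", round(semanticValue(object), 4), "\n", sep = "")
})
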