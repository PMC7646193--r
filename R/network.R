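#' Load the heterogeneous miRNA-protein-disease network
#'
#' Builds a [HeteroNetwork-class] from two association edge lists:
#' miRNA-protein and protein-disease. Node kinds are inferred from the
#' column/file an identifier appears in (column 1 of the first list =
#' miRNA, column 2 of the first and column 1 of the second = protein,
#' column 2 of the second = disease). Duplicate records collapse to a
#' single edge. Identifiers are whitespace-trimmed and matched exactly,
#' case preserved.
#'
#' Nodes are indexed miRNA block first, then proteins, then diseases,
#' each block sorted lexicographically (C collation), which makes every
#' downstream embedding reproducible across runs. An optional node
#' manifest can declare isolated nodes (retained with all-zero rows).
#'
#' @param mirnaProtein edge-list source for miRNA-protein associations:
#'   a TSV path (two columns, `#` comments allowed) or a two-column
#'   data.frame.
#' @param proteinDisease edge-list source for protein-disease
#'   associations, same formats.
#' @param nodeManifest optional TSV path or data.frame with columns
#'   (id, kind) declaring nodes that may appear in no edge.
#' @return a validated [HeteroNetwork-class] object.
#' @examples
#' mp <- data.frame(mirna = "m1", protein = "p1")
#' pd <- data.frame(protein = "p1", disease = "d1")
#' net <- loadNetwork(mp, pd)
#' networkSummary(net)
#' @export
loadNetwork <- function(mirnaProtein, proteinDisease, nodeManifest = NULL) {
  mp <- .readEdgeList(mirnaProtein, "miRNA-protein edges")
  pd <- .readEdgeList(proteinDisease, "protein-disease edges")
  if (any(mp$from == mp$to) || any(pd$from == pd$to))
    stop("self-pairs are not allowed", call. = FALSE)

  ids <- list(miRNA = unique(mp$from),
              protein = unique(c(mp$to, pd$from)),
              disease = unique(pd$to))
  if (!is.null(nodeManifest)) {
    man <- .readEdgeList(nodeManifest, "node manifest")
    names(man) <- c("id", "kind")
    if (!all(man$kind %in% names(ids)))
      stop("node manifest: unknown kind '",
           setdiff(man$kind, names(ids))[1L], "'", call. = FALSE)
    for (k in names(ids))
      ids[[k]] <- unique(c(ids[[k]], man$id[man$kind == k]))
  }
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    clash <- intersect(ids[[a]], ids[[b]])
    if (length(clash))
      stop("identifier '", clash[1L], "' appears as both ",
           names(ids)[a], " and ", names(ids)[b], call. = FALSE)
  }
  loc <- Sys.getlocale("LC_COLLATE"); Sys.setlocale("LC_COLLATE", "C")
  on.exit(Sys.setlocale("LC_COLLATE", loc), add = TRUE)
  nodes <- data.frame(
    id = c(sort(ids$miRNA), sort(ids$protein), sort(ids$disease)),
    kind = rep(c("miRNA", "protein", "disease"), lengths(ids)),
    stringsAsFactors = FALSE)
  nodes$index <- seq_len(nrow(nodes))

  edges <- unique(rbind(mp, pd))
  i <- match(edges$from, nodes$id)
  j <- match(edges$to, nodes$id)
  N <- nrow(nodes)
  S <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(N, N), dimnames = list(nodes$id, nodes$id))
  S@x[] <- 1  # a record and its mirror collapse to a single 0/1 entry
  new("HeteroNetwork", nodes = nodes, adjacency = S)
}

#' Summarise a heterogeneous network
#'
#' @param net a [HeteroNetwork-class] object.
#' @return list with `nodeCounts` (named: miRNA, protein, disease,
#'   total) and `edgeCounts` (named: miRNA-protein, protein-disease,
#'   total).
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "HeteroNetwork"))
  nd <- net@nodes
  nc <- c(miRNA = sum(nd$kind == "miRNA"),
          protein = sum(nd$kind == "protein"),
          disease = sum(nd$kind == "disease"))
  nc <- c(nc, total = sum(nc))
  ij <- Matrix::which(net@adjacency != 0, arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  kinds <- paste(pmin(nd$kind[ij[, 1]], nd$kind[ij[, 2]]),
                 pmax(nd$kind[ij[, 1]], nd$kind[ij[, 2]]), sep = "-")
  ec <- c(`miRNA-protein` = sum(kinds == "miRNA-protein"),
          `protein-disease` = sum(kinds == "disease-protein"))
  ec <- c(ec, total = sum(ec))
  list(nodeCounts = nc, edgeCounts = ec)
}

#' Extract the unique undirected edge set of a network
#'
#' @param net a [HeteroNetwork-class] object.
#' @return data.frame with columns `from`, `to` (from has the lower
#'   node index; one row per undirected edge).
#' @export
networkEdges <- function(net) {
  stopifnot(is(net, "HeteroNetwork"))
  ij <- Matrix::which(net@adjacency != 0, arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  data.frame(from = net@nodes$id[ij[, 1]], to = net@nodes$id[ij[, 2]],
             stringsAsFactors = FALSE)
}

#' Write a network to a directory
#'
#' Writes `nodes.tsv` (id, kind), `edges.tsv` (sparse triplet:
#' from, to) and `summary.txt` (key: value lines).
#'
#' @param net a [HeteroNetwork-class] object.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeNetwork <- function(net, dir) {
  stopifnot(is(net, "HeteroNetwork"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(net@nodes[, c("id", "kind")], file.path(dir, "nodes.tsv"))
  .writeTsv(networkEdges(net), file.path(dir, "edges.tsv"))
  s <- networkSummary(net)
  kv <- c(sprintf("nodes.%s: %d", names(s$nodeCounts), s$nodeCounts),
          sprintf("edges.%s: %d", names(s$edgeCounts), s$edgeCounts))
  writeLines(kv, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Read back a network written by [writeNetwork()]
#'
#' @param dir directory containing `nodes.tsv` and `edges.tsv`.
#' @return a [HeteroNetwork-class] object.
#' @export
readNetwork <- function(dir) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(file.path(dir, "edges.tsv"),
                             stringsAsFactors = FALSE)
  kind <- nodes$kind[match(edges$from, nodes$id)]
  mp <- edges[kind == "miRNA", ]
  pd <- edges[kind == "protein", ]
  loadNetwork(mp, pd, nodeManifest = nodes)
}

#' @describeIn networkSummary compact display of a network
#' @param object a [HeteroNetwork-class] object.
#' @export
setMethod("show", "HeteroNetwork", function(object) {
  s <- networkSummary(object)
  cat("HeteroNetwork:", s$nodeCounts[["total"]], "nodes (",
      s$nodeCounts[["miRNA"]], "miRNA,", s$nodeCounts[["protein"]],
      "protein,", s$nodeCounts[["disease"]], "disease ),",
      s$edgeCounts[["total"]], "edges\n")
})

#' Node ids of a network
#' @param net a [HeteroNetwork-class] object.
#' @param kind optional kind filter (`"miRNA"`, `"protein"`, `"disease"`).
#' @return character vector of ids in node order.
#' @export
nodeIds <- function(net, kind = NULL) {
  stopifnot(is(net, "HeteroNetwork"))
  if (is.null(kind)) return(net@nodes$id)
  net@nodes$id[net@nodes$kind == kind]
}
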