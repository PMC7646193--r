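#' One-step transition probability matrix of a network
#'
#' Row-normalises the adjacency, `A = D^-1 S`, where `D` is the degree
#' matrix. Isolated nodes keep an all-zero row (no teleportation); a
#' warning lists how many there are.
#'
#' @param net a [HeteroNetwork-class] object.
#' @return dense numeric N x N matrix with entries in [0, 1]; rows of
#'   positive-degree nodes sum to 1.
#' @export
transitionMatrix <- function(net) {
  stopifnot(is(net, "HeteroNetwork"))
  S <- as.matrix(net@adjacency)
  deg <- rowSums(S)
  iso <- sum(deg == 0)
  if (iso > 0)
    warning(iso, " isolated node(s) receive all-zero transition rows")
  inv <- ifelse(deg > 0, 1 / deg, 0)
  A <- S * inv            # recycles inv down columns = row scaling
  dimnames(A) <- dimnames(S)
  A
}

#' k-step transition probability matrix
#'
#' The k-th matrix power of the one-step transition matrix: entry (i, j)
#' is the probability that a k-hop random walk started at i ends at j.
#'
#' @param A one-step transition matrix from [transitionMatrix()].
#' @param k step count, integer >= 1.
#' @return numeric matrix `A^k`.
#' @export
kStepMatrix <- function(A, k) {
  stopifnot(k >= 1)
  Ak <- A
  if (k > 1) for (i in seq_len(k - 1)) Ak <- Ak %*% A
  Ak
}

#' Positive log probability matrix
#'
#' Column-normalises `A^k` by `Gamma_j = sum_p A^k[p, j]`, takes
#' elementwise logs shifted by `-log(beta)`, and clips negative entries
#' to zero: `X[i, j] = max(0, log(A^k[i, j] / Gamma_j) - log(beta))`.
#' Entries with `A^k[i, j] = 0` (log of zero is a negative infinity,
#' clipped) and zero columns (`Gamma_j = 0`, isolated nodes) are 0.
#'
#' @param Ak k-step transition matrix.
#' @param beta log shift factor, > 0.
#' @return nonnegative finite matrix of the same shape.
#' @export
positiveLogProb <- function(Ak, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a single positive number", call. = FALSE)
  gamma <- colSums(Ak)
  X <- matrix(0, nrow(Ak), ncol(Ak), dimnames = dimnames(Ak))
  pos <- which(Ak > 0 & rep(gamma > 0, each = nrow(Ak)))
  if (length(pos)) {
    j <- ((pos - 1L) %/% nrow(Ak)) + 1L
    X[pos] <- pmax(0, log(Ak[pos] / gamma[j]) - log(beta))
  }
  X
}

#' Factorise one positive log probability matrix
#'
#' Truncated SVD step: `W^k = U_d (Sigma_d)^(1/2)`. Each singular
#' vector's sign is fixed so its largest-magnitude component is positive
#' (ties to the lowest index), making the representation deterministic.
#'
#' @param Xk nonnegative matrix from [positiveLogProb()].
#' @param d representation dimension, 1 <= d <= N.
#' @return N x d numeric matrix.
#' @export
factorizeStep <- function(Xk, d) {
  N <- nrow(Xk)
  if (d < 1 || d > N)
    stop("d must lie in [1, N]", call. = FALSE)
  if (all(Xk == 0)) {
    W <- matrix(0, N, d)
    rownames(W) <- rownames(Xk)
    return(W)
  }
  s <- svd(Xk, nu = d, nv = 0)
  u <- .fixSvdSigns(s$u)
  W <- u %*% diag(sqrt(s$d[seq_len(d)]), nrow = d)
  rownames(W) <- rownames(Xk)
  W
}

#' GraRep global structural embedding of a heterogeneous network
#'
#' Runs the full GraRep pipeline: row-normalised transitions, matrix
#' powers `A^1 .. A^K`, log-shifted column-normalised probabilities with
#' negatives clipped to zero, truncated SVD per step, and horizontal
#' concatenation `W = [W^1 | ... | W^K]`. The result is fully
#' deterministic for a given network and configuration.
#'
#' @param net a [HeteroNetwork-class] object.
#' @param K maximum transition step (default 2).
#' @param d per-step representation dimension (default 16, giving 32
#'   behavior dimensions per node under the defaults).
#' @param beta log shift factor; defaults to `1/N` where N is the node
#'   count, the usual GraRep convention.
#' @return a [GraRepEmbedding-class] with an N x (K*d) matrix.
#' @examples
#' mp <- data.frame(m = c("m1", "m2"), p = c("p1", "p1"))
#' pd <- data.frame(p = "p1", d = "d1")
#' net <- loadNetwork(mp, pd)
#' emb <- graRepEmbed(net, K = 2, d = 2)
#' dim(embeddingMatrix(emb))
#' @export
graRepEmbed <- function(net, K = 2L, d = 16L, beta = NULL) {
  stopifnot(is(net, "HeteroNetwork"), K >= 1, d >= 1)
  N <- nrow(net@nodes)
  if (d > N) stop("d must not exceed the node count", call. = FALSE)
  if (is.null(beta)) beta <- 1 / N
  A <- suppressWarnings(transitionMatrix(net))
  Ak <- A
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    if (k > 1) Ak <- Ak %*% A
    Xk <- positiveLogProb(Ak, beta)
    blocks[[k]] <- factorizeStep(Xk, d)
  }
  W <- do.call(cbind, blocks)
  rownames(W) <- net@nodes$id
  new("GraRepEmbedding", W = W, nodeKinds = net@nodes$kind,
      K = as.integer(K), d = as.integer(d), beta = beta)
}

#' Embedding matrix accessor
#' @param emb a [GraRepEmbedding-class] object.
#' @return the N x (K*d) matrix, rownames = node ids.
#' @export
embeddingMatrix <- function(emb) {
  stopifnot(is(emb, "GraRepEmbedding"))
  emb@W
}

#' Write an embedding as TSV (node_id, kind, then K*d float columns)
#' @param emb a [GraRepEmbedding-class] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeEmbedding <- function(emb, path) {
  stopifnot(is(emb, "GraRepEmbedding"))
  df <- data.frame(node_id = rownames(emb@W), kind = emb@nodeKinds,
                   emb@W, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-(1:2)] <- paste0("w", seq_len(ncol(emb@W)))
  .writeTsv(df, path)
  invisible(path)
}

#' @describeIn embeddingMatrix compact display
#' @param object a [GraRepEmbedding-class] object.
#' @export
setMethod("show", "GraRepEmbedding", function(object) {
  cat("GraRepEmbedding:", nrow(object@W), "nodes x", ncol(object@W),
      "dims (K =", object@K, ", d =", object@d,
      ", beta =", signif(object@beta, 4), ")\n")
})
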