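# Shared fixtures and independent oracles.

# path graph m1 - p1 - d1 (degrees 1, 2, 1)
pathNetwork <- function() {
  loadNetwork(data.frame(from = "m1", to = "p1"),
              data.frame(from = "p1", to = "d1"))
}

# random small heterogeneous network; every node gets at least one edge
randomSmallNetwork <- function(nM = 4, nP = 5, nD = 3, p = 0.4, seed = 1) {
  set.seed(seed)
  mir <- paste0("m", seq_len(nM))
  pro <- paste0("p", seq_len(nP))
  dis <- paste0("d", seq_len(nD))
  draw <- function(a, b) {
    hit <- matrix(runif(length(a) * length(b)) < p, length(a), length(b))
    for (i in which(rowSums(hit) == 0)) hit[i, sample(length(b), 1)] <- TRUE
    for (j in which(colSums(hit) == 0)) hit[sample(length(a), 1), j] <- TRUE
    ij <- which(hit, arr.ind = TRUE)
    data.frame(from = a[ij[, 1]], to = b[ij[, 2]])
  }
  loadNetwork(draw(mir, pro), draw(pro, dis))
}

# Independent dense GraRep oracle: explicit loops for the transition
# and log-probability steps, eigendecomposition of X X^T for the SVD
# factor (a different route than the production svd() call).
oracleGraRep <- function(S, K, d, beta) {
  S <- as.matrix(S)
  N <- nrow(S)
  deg <- rowSums(S)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) if (deg[i] > 0) A[i, ] <- S[i, ] / deg[i]
  W <- NULL
  Ak <- diag(N)
  for (k in seq_len(K)) {
    Ak <- Ak %*% A
    X <- matrix(0, N, N)
    for (j in seq_len(N)) {
      g <- sum(Ak[, j])
      if (g > 0) for (i in seq_len(N)) if (Ak[i, j] > 0)
        X[i, j] <- max(0, log(Ak[i, j] / g) - log(beta))
    }
    if (all(X == 0)) {
      Wk <- matrix(0, N, d)
    } else {
      e <- eigen(X %*% t(X), symmetric = TRUE)
      sv <- sqrt(pmax(e$values, 0))   # singular values of X
      U <- e$vectors[, seq_len(d), drop = FALSE]
      Wk <- U %*% diag(sqrt(sv[seq_len(d)]), nrow = d)
    }
    W <- cbind(W, Wk)
  }
  W
}

# Align column signs of B to A, then return max absolute difference.
maxDiffAligned <- function(A, B) {
  stopifnot(dim(A) == dim(B))
  for (j in seq_len(ncol(A))) {
    if (sum(A[, j] * B[, j]) < 0) B[, j] <- -B[, j]
  }
  max(abs(A - B))
}

# simple linear ontology R -> P -> {B, C}: two sibling diseases
siblingOntology <- function() {
  c(R = "R", R.1 = "P", R.1.1 = "C", R.1.2 = "B")
}

# random disease DAG pair over a shared random tree of dotted codes
randomDagPair <- function(seed, delta = 0.5) {
  set.seed(seed)
  # tree: root T, two children T.1 T.2, four grandchildren
  codes <- c("T", "T.1", "T.2", "T.1.1", "T.1.2", "T.2.1", "T.2.2")
  ont <- setNames(paste0("n", seq_along(codes)), codes)
  leaves <- c("T.1.1", "T.1.2", "T.2.1", "T.2.2")
  pick <- sample(leaves, 2, replace = TRUE)
  # override the picked leaf's term with the disease id (first match wins)
  dagA <- buildDiseaseDAG("A", pick[1], c(setNames("A", pick[1]), ont),
                          delta = delta)
  dagB <- buildDiseaseDAG("B", pick[2], c(setNames("B", pick[2]), ont),
                          delta = delta)
  list(A = dagA, B = dagB)
}

tinyWorld <- function(signal = 1, seed = 1) {
  generateWorld(nMirna = 16, nProtein = 24, nDisease = 12, nGroups = 4,
                signal = signal, seed = seed)
}
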