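# hand-derived matrices for the path graph m1 - p1 - d1 (node order
# m1, p1, d1; degrees 1, 2, 1)
pathA <- matrix(c(0, 0.5, 0,
                  1, 0,   1,
                  0, 0.5, 0), 3, 3)

test_that("transition matrix is the degree-normalised adjacency", {
  A <- transitionMatrix(pathNetwork())
  expect_equal(unname(A), pathA, tolerance = 1e-12)
  # complete-ish symmetric case: every protein neighbour gets 1/degree
  net <- loadNetwork(data.frame(from = c("m1", "m2"), to = c("p1", "p1")),
                     data.frame(from = "p1", to = "d1"))
  A2 <- transitionMatrix(net)
  expect_equal(unname(A2["p1", c("m1", "m2", "d1")]), rep(1 / 3, 3))
  expect_true(all(A2 >= 0 & A2 <= 1))
  # isolated node: zero row plus a warning
  netIso <- loadNetwork(data.frame(from = "m1", to = "p1"),
                        data.frame(from = "p1", to = "d1"),
                        nodeManifest = data.frame(id = "m9", kind = "miRNA"))
  expect_warning(Aiso <- transitionMatrix(netIso), "isolated")
  expect_equal(sum(Aiso["m9", ]), 0)
})

test_that("k-step matrices are matrix powers with row sums at most 1", {
  expect_equal(kStepMatrix(pathA, 1), pathA)
  A2 <- kStepMatrix(pathA, 2)
  expect_equal(A2, matrix(c(0.5, 0, 0.5,
                            0,   1, 0,
                            0.5, 0, 0.5), 3, 3), tolerance = 1e-12)
  Z <- matrix(0, 3, 3)
  expect_equal(kStepMatrix(Z, 4), Z)
  for (k in 1:4)
    expect_true(all(rowSums(kStepMatrix(pathA, k)) <= 1 + 1e-12))
})

test_that("positive log probability matches direct formula evaluation", {
  X <- positiveLogProb(pathA, beta = 1 / 3)
  # Gamma = (0.5, 2, 0.5); X[2,1] = log(0.5/0.5) - log(1/3) = log 3
  expect_equal(X[2, 1], log(3), tolerance = 1e-12)
  # X[1,2] = log(1/2) - log(1/3) = log 1.5
  expect_equal(X[1, 2], log(1.5), tolerance = 1e-12)
  expect_true(all(X >= 0) && all(is.finite(X)))
  expect_equal(positiveLogProb(matrix(0, 2, 2), 0.1), matrix(0, 2, 2))
  # beta at least the largest column-normalised entry zeroes everything
  expect_equal(positiveLogProb(pathA, beta = 1), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(positiveLogProb(pathA, beta = 0), "beta")
})

test_that("factorisation matches a dense SVD oracle", {
  expect_equal(factorizeStep(matrix(0, 4, 4), 2), matrix(0, 4, 2))
  WI <- factorizeStep(diag(3), 3)
  expect_equal(abs(WI), diag(3), tolerance = 1e-12)
  set.seed(9)
  X <- matrix(abs(rnorm(36)), 6, 6)
  W <- factorizeStep(X, 2)
  s <- svd(X)
  Wo <- s$u[, 1:2] %*% diag(sqrt(s$d[1:2]))
  expect_lt(maxDiffAligned(W, Wo), 1e-8)
  expect_error(factorizeStep(X, 7), "d must")
})

test_that("full embedding matches the independent dense pipeline", {
  net <- randomSmallNetwork(nM = 4, nP = 4, nD = 2, seed = 3)  # 10 nodes
  emb <- graRepEmbed(net, K = 3, d = 4)
  W <- embeddingMatrix(emb)
  expect_equal(dim(W), c(10L, 12L))
  Wo <- oracleGraRep(net@adjacency, K = 3, d = 4, beta = 1 / 10)
  expect_lt(maxDiffAligned(W, Wo), 1e-8)
  # K = 1 reduces to a single factorised step
  emb1 <- graRepEmbed(net, K = 1, d = 4)
  A <- suppressWarnings(transitionMatrix(net))
  W1 <- factorizeStep(positiveLogProb(A, 1 / 10), 4)
  expect_equal(unname(embeddingMatrix(emb1)), unname(W1), tolerance = 1e-12)
})

test_that("X^k stays nonnegative and finite on random graphs", {
  for (seed in 1:8) {
    net <- randomSmallNetwork(nM = 3 + seed %% 3, nP = 4, nD = 3,
                              p = 0.3, seed = seed)
    A <- suppressWarnings(transitionMatrix(net))
    for (k in 1:3) {
      X <- positiveLogProb(kStepMatrix(A, k), 1 / nrow(A))
      expect_true(all(X >= 0) && all(is.finite(X)))
    }
  }
})

test_that("embedding is equivariant under node relabeling", {
  net <- randomSmallNetwork(nM = 4, nP = 5, nD = 3, seed = 7)
  # rename so that the lexicographic order within each block reverses
  flip <- function(ids) setNames(ids[seq(length(ids), 1)], ids)
  map <- c(flip(nodeIds(net, "miRNA")), flip(nodeIds(net, "protein")),
           flip(nodeIds(net, "disease")))
  e <- networkEdges(net)
  kind <- net@nodes$kind[match(e$from, net@nodes$id)]
  e$from <- unname(map[e$from]); e$to <- unname(map[e$to])
  net2 <- loadNetwork(e[kind == "miRNA", ], e[kind == "protein", ])
  W1 <- embeddingMatrix(graRepEmbed(net, K = 2, d = 3))
  W2 <- embeddingMatrix(graRepEmbed(net2, K = 2, d = 3))
  expect_lt(maxDiffAligned(W1, W2[map[rownames(W1)], ]), 1e-8)
})

test_that("structurally identical nodes embed with equal norm", {
  # m1 and m2 attach to exactly the same proteins
  net <- loadNetwork(data.frame(from = c("m1", "m1", "m2", "m2"),
                                to = c("p1", "p2", "p1", "p2")),
                     data.frame(from = c("p1", "p2"), to = c("d1", "d1")))
  W <- embeddingMatrix(graRepEmbed(net, K = 2, d = 3))
  expect_equal(sum(W["m1", ]^2), sum(W["m2", ]^2), tolerance = 1e-10)
})
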