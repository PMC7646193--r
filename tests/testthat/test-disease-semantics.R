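test_that("DAG construction follows the dotted-code hierarchy", {
  ont <- c(C04 = "NeoplasmsBySite", C04.588 = "LungN")
  dag <- buildDiseaseDAG("LungN", "C04.588", ont)
  expect_setequal(dag@nodes, c("NeoplasmsBySite", "LungN"))
  expect_equal(nrow(dag@edges), 1)
  # two tree numbers sharing an ancestor: ancestor appears once
  ont2 <- c(A = "rootA", A.1 = "mid1", A.2 = "mid2",
            A.1.1 = "X", A.2.1 = "X")
  dag2 <- buildDiseaseDAG("X", c("A.1.1", "A.2.1"), ont2)
  expect_equal(sum(dag2@nodes == "rootA"), 1)
  expect_setequal(dag2@nodes, c("rootA", "mid1", "mid2", "X"))
  expect_error(buildDiseaseDAG("X", "B.9", ont2), "unknown tree number")
})

test_that("semantic contributions decay by delta along ancestor paths", {
  ont <- c(R = "R", R.1 = "P", R.1.1 = "C")
  dag <- buildDiseaseDAG("C", "R.1.1", ont, delta = 0.5)
  cc <- dag@contributions
  expect_equal(cc[["C"]], 1)
  expect_equal(cc[["P"]], 0.5)
  expect_equal(cc[["R"]], 0.25)
  # delta = 1 disables decay
  cc1 <- semanticContribution(dag, delta = 1)
  expect_true(all(cc1 == 1))
  # diamond: two parents of C sharing grandparent G -> max rule
  ontD <- c(G = "G", G.1 = "P1", G.2 = "P2", G.1.1 = "C", G.2.1 = "C")
  dagD <- buildDiseaseDAG("C", c("G.1.1", "G.2.1"), ontD, delta = 0.5)
  expect_equal(dagD@contributions[["G"]], 0.25)
  expect_equal(dagD@contributions[["P1"]], 0.5)
})

test_that("semantic values add contributions over the DAG", {
  ont <- c(R = "R", R.1 = "P", R.1.1 = "C")
  dag <- buildDiseaseDAG("C", "R.1.1", ont, delta = 0.5)
  expect_equal(semanticValue(dag), 1.75)
  lone <- buildDiseaseDAG("solo", character(), c(X = "X"))
  expect_equal(semanticValue(lone), 1)
  # delta = 1 on an n-node chain gives n
  ontN <- c(a = "n1", a.b = "n2", a.b.c = "n3", a.b.c.d = "n4")
  dagN <- buildDiseaseDAG("n4", "a.b.c.d", ontN, delta = 1)
  expect_equal(semanticValue(dagN), 4)
})

test_that("similarity matches hand evaluation and its boundary cases", {
  ont <- siblingOntology()
  dagC <- buildDiseaseDAG("C", "R.1.1", ont, delta = 0.5)
  dagB <- buildDiseaseDAG("B", "R.1.2", ont, delta = 0.5)
  # shared {P, R}: (0.5 + 0.25) * 2 / (1.75 + 1.75) = 1.5 / 3.5
  expect_equal(semanticSimilarity(dagB, dagC), 1.5 / 3.5)
  expect_equal(semanticSimilarity(dagC, dagB), 1.5 / 3.5)
  expect_equal(semanticSimilarity(dagC, dagC), 1)
  other <- buildDiseaseDAG("Z", "Q.1", c(Q = "Q", Q.1 = "Z"), delta = 0.5)
  expect_equal(semanticSimilarity(dagC, other), 0)
  expect_error(semanticSimilarity(dagC,
    buildDiseaseDAG("B", "R.1.2", ont, delta = 0.9)), "same delta")
})

test_that("similarity matrix is symmetric, unit-diagonal and consistent", {
  ont <- siblingOntology()
  dags <- list(C = buildDiseaseDAG("C", "R.1.1", ont),
               B = buildDiseaseDAG("B", "R.1.2", ont))
  SS <- diseaseSimilarityMatrix(dags)
  expect_equal(diag(SS), c(C = 1, B = 1))
  expect_equal(SS["C", "B"], 1.5 / 3.5)
  expect_equal(SS, t(SS))
  expect_equal(diseaseSimilarityMatrix(dags["C"]),
               matrix(1, 1, 1, dimnames = list("C", "C")))
  # entrywise agreement with pairwise calls
  for (i in 1:2) for (j in 1:2)
    expect_equal(SS[i, j], semanticSimilarity(dags[[i]], dags[[j]]))
  # mutually disjoint diseases give the identity
  dis <- list(a = buildDiseaseDAG("a", "U.1", c(U = "u", U.1 = "a")),
              b = buildDiseaseDAG("b", "V.1", c(V = "v", V.1 = "b")))
  expect_equal(unname(diseaseSimilarityMatrix(dis)), diag(2))
})

test_that("delta -> 1 limit equals the shared-node count formula", {
  for (seed in 1:50) {
    pair <- randomDagPair(seed, delta = 1)
    shared <- length(intersect(pair$A@nodes, pair$B@nodes))
    expected <- 2 * shared / (length(pair$A@nodes) + length(pair$B@nodes))
    got <- semanticSimilarity(pair$A, pair$B)
    if (setequal(pair$A@nodes, pair$B@nodes) &&
        pair$A@disease == pair$B@disease) {
      expect_equal(got, 1)
    } else {
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
})

test_that("contributions dominate the geometric bound along paths", {
  for (seed in 1:10) {
    pair <- randomDagPair(seed, delta = 0.4)
    dag <- pair$A
    # every node at depth h (shortest path to the disease) has
    # contribution >= delta^h; on a single-path chain it is exact
    cc <- dag@contributions
    expect_true(all(cc > 0 & cc <= 1))
    expect_equal(cc[[dag@disease]], 1)
  }
  ont <- c(R = "R", R.1 = "P", R.1.1 = "C")
  dag <- buildDiseaseDAG("C", "R.1.1", ont, delta = 0.3)
  expect_equal(unname(dag@contributions[c("C", "P", "R")]),
               c(1, 0.3, 0.09))
})

test_that("diseases without tree numbers get singleton DAGs", {
  lone <- buildDiseaseDAG("orphan", character(), c(X = "X"))
  expect_identical(lone@nodes, "orphan")
  ont <- siblingOntology()
  dagC <- buildDiseaseDAG("C", "R.1.1", ont)
  expect_equal(semanticSimilarity(lone, dagC), 0)
  expect_equal(semanticSimilarity(lone, lone), 1)
})
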