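#' Generate a synthetic world with a planted association signal
#'
#' Builds a self-contained data set for the whole pipeline: a
#' heterogeneous miRNA-protein-disease network, miRNA sequences,
#' disease ontology descriptors and known positive pairs. A hidden
#' partition into `nGroups` groups links miRNA groups to disease groups
#' through shared protein hubs, and `signal` in [0, 1] controls how
#' strongly every data layer reflects that partition:
#'
#' * network edges: within-group probability interpolates from
#'   `edgeDensity` (signal 0) to 0.6, cross-group from `edgeDensity`
#'   to 0.02 — at signal 0 wiring is uniform, at signal 1 protein hubs
#'   are group-private;
#' * positives: a within-group miRNA-disease pair is positive with
#'   probability `signal * w_g`, where the group factors `w_g` spread
#'   evenly over [0.6, 1] (annotation density differs across disease
#'   areas in real catalogues); a cross-group pair is positive with
#'   probability `(1 - signal) / nGroups`;
#' * sequences: per-base composition interpolates from uniform to a
#'   group-specific biased profile, so 3-mer attributes carry the group;
#' * disease DAGs: each disease attaches under its own group's ontology
#'   subtree with probability `signal`, otherwise under a random one.
#'
#' At signal 0 nothing about a pair predicts its label (cross-validated
#' AUC ~ 0.5); at signal 1 group membership determines the label and is
#' recoverable from every feature channel. All randomness flows from
#' the single seed, and generated files are byte-identical per seed.
#'
#' @param nMirna,nProtein,nDisease entity counts (defaults 60/120/40).
#' @param nGroups number of planted groups, default 4.
#' @param edgeDensity baseline edge probability in (0, 1), default 0.15.
#' @param signal planted signal strength in [0, 1], default 1.
#' @param seed integer seed.
#' @return a [SyntheticWorld-class] object.
#' @examples
#' w <- generateWorld(nMirna = 12, nProtein = 20, nDisease = 8, seed = 7)
#' w@network
#' @export
generateWorld <- function(nMirna = 60L, nProtein = 120L, nDisease = 40L,
                          nGroups = 4L, edgeDensity = 0.15, signal = 1,
                          seed = 1L) {
  if (min(nMirna, nProtein, nDisease) < nGroups)
    stop("each entity count must be at least nGroups", call. = FALSE)
  stopifnot(edgeDensity > 0, edgeDensity < 1, signal >= 0, signal <= 1)
  mir <- sprintf("mir-%03d", seq_len(nMirna))
  pro <- sprintf("prot-%03d", seq_len(nProtein))
  dis <- sprintf("dis-%03d", seq_len(nDisease))
  grp <- function(n) ((seq_len(n) - 1L) %% nGroups) + 1L
  gM <- grp(nMirna); gP <- grp(nProtein); gD <- grp(nDisease)

  wIn <- (1 - signal) * edgeDensity + signal * 0.6
  wOut <- (1 - signal) * edgeDensity + signal * 0.02

  .withSeed(seed, {
    drawEdges <- function(a, b, ga, gb) {
      same <- outer(ga, gb, `==`)
      p <- ifelse(same, wIn, wOut)
      hit <- matrix(stats::runif(length(a) * length(b)) < p,
                    length(a), length(b))
      # every node keeps at least one edge so the network has no
      # isolated rows unless the user asks for them
      for (i in which(rowSums(hit) == 0))
        hit[i, sample(length(b), 1L)] <- TRUE
      for (j in which(colSums(hit) == 0))
        hit[sample(length(a), 1L), j] <- TRUE
      ij <- which(hit, arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
      data.frame(from = a[ij[, 1]], to = b[ij[, 2]],
                 stringsAsFactors = FALSE)
    }
    mp <- drawEdges(mir, pro, gM, gP)
    pd <- drawEdges(pro, dis, gP, gD)

    # group-specific within rates: annotation density differs across
    # disease areas in real catalogues, and the resulting marginal
    # (main-effect) structure is what tree ensembles exploit at
    # partial signal, where the pure group interaction alone is weak
    wg <- seq(0.6, 1, length.out = nGroups)
    pPos <- ifelse(outer(gM, gD, `==`), signal * wg[gM],
                   (1 - signal) / nGroups)
    hit <- matrix(stats::runif(nMirna * nDisease) < pPos, nMirna, nDisease)
    ij <- which(hit, arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    positives <- data.frame(mirna = mir[ij[, 1]], disease = dis[ij[, 2]],
                            stringsAsFactors = FALSE)

    # sequences: group-biased base composition mixed toward uniform
    base <- c("A", "C", "G", "U")
    profiles <- lapply(seq_len(nGroups), function(g) {
      p <- rep(0.15, 4); p[((g - 1L) %% 4L) + 1L] <- 0.55; p
    })
    seqs <- vapply(seq_len(nMirna), function(i) {
      p <- (1 - signal) * rep(0.25, 4) + signal * profiles[[gM[i]]]
      paste(sample(base, 22L, replace = TRUE, prob = p), collapse = "")
    }, "")
    names(seqs) <- mir

    # ontology: one subtree per group (root + 2 intermediates); each
    # disease hangs under an intermediate of its (or a random) subtree
    rows <- list()
    for (g in seq_len(nGroups)) {
      root <- sprintf("G%02d", g)
      rows[[length(rows) + 1L]] <- data.frame(
        tree_number = c(root, paste0(root, ".1"), paste0(root, ".2")),
        term_id = c(paste0("node-", root),
                    paste0("node-", root, "-1"), paste0("node-", root, "-2")),
        stringsAsFactors = FALSE)
    }
    useOwn <- stats::runif(nDisease) < signal
    homeGrp <- ifelse(useOwn, gD, sample(nGroups, nDisease, replace = TRUE))
    branch <- sample(2L, nDisease, replace = TRUE)
    for (j in seq_len(nDisease))
      rows[[length(rows) + 1L]] <- data.frame(
        tree_number = sprintf("G%02d.%d.%d", homeGrp[j], branch[j], j),
        term_id = dis[j], stringsAsFactors = FALSE)
    descriptors <- do.call(rbind, rows)
    descriptors <- descriptors[order(descriptors$tree_number), ]
    rownames(descriptors) <- NULL

    net <- loadNetwork(mp, pd)
    new("SyntheticWorld", network = net, sequences = seqs,
        descriptors = descriptors, positives = positives,
        truth = list(mirna = stats::setNames(gM, mir),
                     protein = stats::setNames(gP, pro),
                     disease = stats::setNames(gD, dis)),
        signal = signal, seed = as.integer(seed))
  })
}

#' Generate a synthetic association manifest of a given size
#'
#' Draws distinct miRNA-protein and protein-disease association records
#' uniformly (after forcing every node into at least one record, so the
#' node counts are exact). Defaults mirror the scale of the public
#' catalogues the method is designed for: 271 miRNAs, 1147 proteins and
#' 693 diseases linked by 4944 miRNA-protein and 25,087 protein-disease
#' associations.
#'
#' @param nMirna,nProtein,nDisease node counts.
#' @param nMirnaProtein,nProteinDisease record counts per association
#'   type.
#' @param seed integer seed.
#' @return list with data.frames `mirnaProtein` and `proteinDisease`,
#'   ready for [loadNetwork()].
#' @export
generateManifest <- function(nMirna = 271L, nProtein = 1147L,
                             nDisease = 693L, nMirnaProtein = 4944L,
                             nProteinDisease = 25087L, seed = 1L) {
  drawPairs <- function(a, b, n) {
    nA <- length(a); nB <- length(b)
    stopifnot(n >= max(nA, nB), n <= nA * nB)
    # force coverage of every node, then fill with uniform extras
    forced <- unique(c((seq_len(nA) - 1L) * nB +
                         ((seq_len(nA) - 1L) %% nB + 1L),
                       (((seq_len(nB) - 1L) %% nA)) * nB + seq_len(nB)))
    pool <- setdiff(seq_len(nA * nB), forced)
    extra <- pool[sample.int(length(pool), n - length(forced))]
    idx <- sort(c(forced, extra))
    data.frame(from = a[(idx - 1L) %/% nB + 1L],
               to = b[(idx - 1L) %% nB + 1L], stringsAsFactors = FALSE)
  }
  .withSeed(seed, {
    mir <- sprintf("mir-%04d", seq_len(nMirna))
    pro <- sprintf("prot-%04d", seq_len(nProtein))
    dis <- sprintf("dis-%04d", seq_len(nDisease))
    list(mirnaProtein = drawPairs(mir, pro, nMirnaProtein),
         proteinDisease = drawPairs(pro, dis, nProteinDisease))
  })
}

#' Write a synthetic world's input files
#'
#' Writes, in the formats the loaders consume: `mirna_protein.tsv`,
#' `protein_disease.tsv`, `positives.tsv`, `sequences.fasta`,
#' `descriptors.tsv`. Output is deterministic (byte-identical for equal
#' seeds).
#'
#' @param world a [SyntheticWorld-class] object.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeWorld <- function(world, dir) {
  stopifnot(is(world, "SyntheticWorld"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- networkEdges(world@network)
  kind <- world@network@nodes$kind[match(edges$from, world@network@nodes$id)]
  rownames(edges) <- NULL
  .writePairFile(edges[kind == "miRNA", ],
                 file.path(dir, "mirna_protein.tsv"))
  .writePairFile(edges[kind == "protein", ],
                 file.path(dir, "protein_disease.tsv"))
  .writePairFile(world@positives, file.path(dir, "positives.tsv"))
  writeMirnaFasta(world@sequences, file.path(dir, "sequences.fasta"))
  .writePairFile(world@descriptors, file.path(dir, "descriptors.tsv"))
  invisible(dir)
}

#' @describeIn generateWorld compact display
#' @param object a [SyntheticWorld-class] object.
#' @export
setMethod("show", "SyntheticWorld", function(object) {
  s <- networkSummary(object@network)
  cat("SyntheticWorld: signal =", object@signal, ", seed =", object@seed,
      "\n  network:", s$nodeCounts[["total"]], "nodes /",
      s$edgeCounts[["total"]], "edges;",
      nrow(object@positives), "positive pairs;",
      length(unique(object@truth$mirna)), "groups\n")
})
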