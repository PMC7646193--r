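# Internal helpers shared across modules.

# Read a two-column TSV edge list; '#' lines are comments. `what` names
# the file in error messages. Returns a data.frame of trimmed character
# columns; errors carry the offending line number.
.readEdgeList <- function(x, what = "edge list") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L)
      stop(what, ": need two identifier columns", call. = FALSE)
    if (nrow(x) == 0L)
      stop(what, ": no records", call. = FALSE)
    df <- data.frame(from = trimws(as.character(x[[1L]])),
                     to = trimws(as.character(x[[2L]])),
                     stringsAsFactors = FALSE)
    bad <- which(df$from == "" | df$to == "" | is.na(df$from) | is.na(df$to))
    if (length(bad))
      stop(what, ": empty identifier in record ", bad[1L], call. = FALSE)
    return(df)
  }
  lines <- readLines(x, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep))
    stop(what, " '", x, "': no records", call. = FALSE)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    i <- keep[which(nf < 2L)[1L]]
    stop(what, " '", x, "': malformed record at line ", i, call. = FALSE)
  }
  from <- trimws(vapply(parts, `[[`, "", 1L))
  to <- trimws(vapply(parts, `[[`, "", 2L))
  bad <- which(from == "" | to == "")
  if (length(bad))
    stop(what, " '", x, "': empty identifier at line ", keep[bad[1L]],
         call. = FALSE)
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# Deterministic SVD sign convention: flip each column of U (and the
# matching column of V) so the entry of largest magnitude is positive;
# ties broken by lowest row index.
.fixSvdSigns <- function(u, v = NULL) {
  flip <- vapply(seq_len(ncol(u)), function(j) {
    col <- u[, j]
    i <- which.max(abs(col))   # which.max returns the first maximum
    if (col[i] < 0) -1 else 1
  }, numeric(1))
  u <- sweep(u, 2L, flip, `*`)
  if (is.null(v)) return(u)
  list(u = u, v = sweep(v, 2L, flip, `*`))
}

# Truncated-SVD row scores: project rows of X onto its top `dim` right
# singular vectors, i.e. U_d %*% diag(sigma_d) under the fixed sign
# convention. Pads with zero columns when rank(X) < dim.
.svdReduce <- function(X, dim) {
  X <- as.matrix(X)
  if (dim < 1L || dim > ncol(X))
    stop("reduction dim must lie in [1, ncol(X)]", call. = FALSE)
  s <- svd(X, nu = min(dim, nrow(X)), nv = 0)
  u <- .fixSvdSigns(s$u)
  k <- ncol(u)
  scores <- u %*% diag(s$d[seq_len(k)], nrow = k)
  if (k < dim)
    scores <- cbind(scores, matrix(0, nrow(X), dim - k))
  rownames(scores) <- rownames(X)
  scores
}

# Evaluate expr under set.seed(seed) without disturbing the caller's
# random-number stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

# Edge-list style TSV with a '#'-prefixed header line, the format the
# loaders consume directly.
.writePairFile <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
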