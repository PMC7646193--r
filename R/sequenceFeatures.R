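#' k-mer composition of an RNA sequence
#'
#' Encodes a sequence as the vector of occurrence frequencies of all
#' `4^k` length-k words over {A, C, G, U} in lexicographic order. The
#' denominator is the window count `L - k + 1`, so the entries of any
#' sequence of length >= k sum to 1; with the default k = 3 this is the
#' 64-dimensional 3-mer composition used as miRNA attribute information.
#'
#' @param sequence RNA string over {A, C, G, U}; T is mapped to U and
#'   case is ignored. Ambiguity codes are rejected (silently skipping
#'   them would distort the denominator).
#' @param k word length, default 3.
#' @return named numeric vector of length `4^k`, entries >= 0 summing
#'   to 1.
#' @examples
#' v <- kmerComposition("UGAC")
#' v[v > 0]   # UGA = 0.5, GAC = 0.5
#' @export
kmerComposition <- function(sequence, k = 3L) {
  stopifnot(length(sequence) == 1L, k >= 1)
  s <- chartr("T", "U", toupper(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  if (length(bad))
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         call. = FALSE)
  L <- length(chars)
  if (L < k)
    stop("sequence length ", L, " is shorter than k = ", k, call. = FALSE)
  alphabet <- c("A", "C", "G", "U")
  grid <- expand.grid(rep(list(alphabet), k),
                      stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  words <- do.call(paste0, grid)  # lexicographic: last position fastest
  counts <- stats::setNames(numeric(length(words)), words)
  win <- vapply(seq_len(L - k + 1L),
                function(i) paste(chars[i:(i + k - 1L)], collapse = ""), "")
  tab <- table(win)
  counts[names(tab)] <- as.numeric(tab)
  counts / (L - k + 1L)
}

#' k-mer composition table for a set of miRNA sequences
#'
#' @param sequences named character vector (id -> sequence), e.g. from
#'   [loadMirnaFasta()].
#' @param k word length, default 3.
#' @return numeric matrix, one row per miRNA, `4^k` columns.
#' @export
kmerTable <- function(sequences, k = 3L) {
  stopifnot(length(sequences) >= 1L, !is.null(names(sequences)))
  t(vapply(sequences, kmerComposition, numeric(4^k), k = k))
}

#' Load miRNA sequences from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header;
#' sequences are uppercased with T mapped to U.
#'
#' @param path FASTA file path.
#' @return named character vector of RNA sequences.
#' @export
loadMirnaFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no records in '", path, "'", call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate miRNA id '", dup[1L], "' in '", path, "'", call. = FALSE)
  seqs <- chartr("T", "U", toupper(as.character(set)))
  if (any(!nzchar(seqs)))
    stop("empty sequence record in '", path, "'", call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#' @param sequences named character vector (id -> sequence).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMirnaFasta <- function(sequences, path) {
  lines <- as.vector(rbind(paste0(">", names(sequences)),
                           unname(sequences)))
  writeLines(lines, path)
  invisible(path)
}
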