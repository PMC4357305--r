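# Pairwise global protein alignment (Gotoh affine-gap DP, compiled) and the
# identity-based distances used for the similarity cladogram.

#' Alignment scoring scheme
#'
#' Conventional protein defaults: BLOSUM62 with affine gap penalties, a gap
#' of length L costing `gap_open + L * gap_extend`.
#'
#' @param matrix substitution matrix name from Biostrings' shipped data
#'   (e.g. "BLOSUM62", "BLOSUM50", "PAM250") or a numeric matrix with
#'   residue-letter dimnames.
#' @param gap_open gap opening penalty (default 10).
#' @param gap_extend per-residue gap extension penalty (default 0.5).
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                          gap_extend = 0.5) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_scoring")
}

encode_seq <- function(seq, letters, what) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, letters)
  if (anyNA(idx)) {
    stop(what, " contains characters absent from the substitution matrix: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Optimal global pairwise alignment
#'
#' Needleman--Wunsch with affine gaps (Gotoh recursion); deterministic
#' traceback tie-breaking (prefer the diagonal move, then up, then left), so
#' repeated runs give identical alignments.
#'
#' @param a,b non-empty protein sequences.
#' @param scoring an [align_scoring()].
#' @return list of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `identity` (fraction of columns
#'   with identical residues).
#' @export
pairwise_align <- function(a, b, scoring = align_scoring()) {
  assert_protein(a, "sequence a")
  assert_protein(b, "sequence b")
  letters <- rownames(scoring$matrix)
  ai <- encode_seq(a, letters, "sequence a")
  bi <- encode_seq(b, letters, "sequence b")
  res <- .gotoh_align(ai, bi, scoring$matrix, scoring$gap_open,
                      scoring$gap_extend)
  dec <- function(idx) {
    out <- letters[pmax(idx, 1L)]
    out[idx == 0L] <- "-"
    paste(out, collapse = "")
  }
  aligned_a <- dec(res$a_idx)
  aligned_b <- dec(res$b_idx)
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  identity <- sum(ca == cb & ca != "-") / length(ca)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = res$score, identity = identity),
            class = "pairwise_alignment")
}

#' Pairwise identity-distance matrix
#'
#' Distance = 1 - fractional identity of the optimal global alignment; each
#' pair is aligned once, so the matrix is symmetric with a zero diagonal by
#' construction.
#'
#' @param seqs named character vector of protein sequences (names become
#'   matrix ids).
#' @param scoring an [align_scoring()].
#' @return symmetric numeric matrix with dimnames.
#' @export
identity_distance_matrix <- function(seqs, scoring = align_scoring()) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- pairwise_align(seqs[[i]], seqs[[j]], scoring)
      d[i, j] <- d[j, i] <- 1 - al$identity
    }
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#' @param d symmetric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
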