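# Center-star progressive multiple alignment built on the pairwise aligner.
# Adequate for the within-clade, high-identity sets it is used on (conserved
# cysteine columns); not a general MSA replacement.

# merge one pairwise alignment (center vs new sequence) into the running MSA
# using "once a gap, always a gap" on the center row
merge_into_msa <- function(msa, center_aligned, new_aligned) {
  cm <- strsplit(msa[[1]], "")[[1]]       # master center row (with gaps)
  ca <- strsplit(center_aligned, "")[[1]] # center row of new alignment
  sa <- strsplit(new_aligned, "")[[1]]
  rows <- lapply(msa, function(s) strsplit(s, "")[[1]])
  out <- vector("list", length(rows) + 1L)
  for (k in seq_along(out)) out[[k]] <- character()
  i <- 1L; j <- 1L
  ni <- length(cm); nj <- length(ca)
  while (i <= ni || j <= nj) {
    if (i <= ni && cm[i] == "-" && (j > nj || ca[j] != "-")) {
      # master-only gap column: existing rows advance, new row gets a gap
      for (k in seq_along(rows)) out[[k]] <- c(out[[k]], rows[[k]][i])
      out[[length(out)]] <- c(out[[length(out)]], "-")
      i <- i + 1L
    } else if (j <= nj && ca[j] == "-") {
      # new-sequence insertion: all existing rows get a gap
      for (k in seq_along(rows)) out[[k]] <- c(out[[k]], "-")
      out[[length(out)]] <- c(out[[length(out)]], sa[j])
      j <- j + 1L
    } else {
      # both carry the same center residue
      for (k in seq_along(rows)) out[[k]] <- c(out[[k]], rows[[k]][i])
      out[[length(out)]] <- c(out[[length(out)]], sa[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  vapply(out, paste, "", collapse = "")
}

#' Center-star multiple alignment
#'
#' Picks the most central sequence (maximum summed pairwise identity,
#' lexicographically first id on ties) as the anchor and merges the pairwise
#' alignments of every other sequence to it, propagating gaps.
#' Deterministic.
#'
#' @param seqs named character vector of >= 2 protein sequences.
#' @param scoring an [align_scoring()].
#' @return named character vector of equal-length gapped sequences, input
#'   order preserved.
#' @export
center_star_msa <- function(seqs, scoring = align_scoring()) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  ids <- names(seqs)
  n <- length(seqs)
  if (n == 2) {
    al <- pairwise_align(seqs[[1]], seqs[[2]], scoring)
    return(stats::setNames(c(al$aligned_a, al$aligned_b), ids))
  }
  idm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- pairwise_align(seqs[[i]], seqs[[j]], scoring)
      idm[i, j] <- idm[j, i] <- al$identity
    }
  }
  tot <- rowSums(idm)
  center <- order(-tot, ids)[1]
  msa <- seqs[[center]]
  order_rest <- setdiff(seq_len(n), center)
  for (j in order_rest) {
    al <- pairwise_align(seqs[[center]], seqs[[j]], scoring)
    msa <- merge_into_msa(as.list(msa), al$aligned_a, al$aligned_b)
  }
  names(msa) <- c(ids[center], ids[order_rest])
  msa[ids]
}

#' Alignment columns where every member has a cysteine
#'
#' @param msa named character vector of equal-length gapped sequences
#'   (>= 2 members).
#' @return integer vector of alignment column indices.
#' @export
conserved_cys_columns <- function(msa) {
  stopifnot(length(msa) >= 2)
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: member lengths differ", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(msa, ""))
  which(apply(mat == "C", 2, all))
}
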