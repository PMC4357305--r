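#' @useDynLib luxrsolo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Amino-acid alphabet used for validation: 20 standard residues plus X.
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

assert_protein <- function(seq, what = "protein sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_LETTERS)
  if (length(bad)) {
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' Write a data frame as a TSV file
#'
#' Plain tab-separated output with a header row, no quoting, `NA` for missing
#' values; the interchange format used between pipeline stages.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV file written by [write_tsv_table()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
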