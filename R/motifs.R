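# AHL-binding / non-AHL-binding motif scanning.  Patterns are PROSITE-style
# expressions kept in an editable TSV config; each sequence gets exactly one
# of the labels AHL / NON_AHL / BOTH / NEITHER.

MOTIF_CLASSES <- c("AHL", "NON_AHL")
MOTIF_LABELS <- c("AHL", "NON_AHL", "BOTH", "NEITHER")

#' Compile a PROSITE-style pattern to a regular expression
#'
#' Supported elements, separated by `-`: literal residues (`W`),
#' alternatives (`[YF]`), exclusions (`{P}`), the wildcard `x`, and repeat
#' counts on any element (`x(3)`, `x(2,4)`).
#'
#' @param pattern PROSITE-style expression.
#' @param pattern_id id used in error messages.
#' @return single regular expression string.
#' @export
compile_prosite <- function(pattern, pattern_id = pattern) {
  elements <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(elements)) {
    stop("empty pattern for ", pattern_id, call. = FALSE)
  }
  parts <- vapply(seq_along(elements), function(i) {
    el <- elements[i]
    rep_re <- "\\(([0-9]+)(,([0-9]+))?\\)$"
    rep_suffix <- ""
    m <- regexpr(rep_re, el)
    if (m > 0) {
      spec <- regmatches(el, m)
      el <- sub(rep_re, "", el)
      spec <- sub("^\\(", "{", sub("\\)$", "}", spec))
      rep_suffix <- spec
    }
    core <- if (el == "x") {
      "[A-Z]"
    } else if (grepl("^\\[[A-Z]+\\]$", el)) {
      el
    } else if (grepl("^\\{[A-Z]+\\}$", el)) {
      paste0("[^", substr(el, 2, nchar(el) - 1), "]")
    } else if (grepl("^[A-Z]+$", el)) {
      el
    } else {
      stop("syntax error in pattern ", pattern_id, " at element ", i,
           ": '", elements[i], "'", call. = FALSE)
    }
    paste0(core, rep_suffix)
  }, character(1))
  paste(parts, collapse = "")
}

#' Parse a motif configuration file
#'
#' TSV with columns `pattern_id`, `class` (AHL or NON_AHL) and `pattern`
#' (PROSITE-style).  Every pattern is compiled at parse time so syntax errors
#' are reported with the offending pattern id.
#'
#' @param path config path; the default is the placeholder config shipped
#'   with the package (see [default_motif_config()]).
#' @return data frame of patterns with a compiled `regex` column.
#' @export
parse_motif_config <- function(path = default_motif_config()) {
  if (!file.exists(path)) stop("motif config not found: ", path,
                               call. = FALSE)
  df <- if (file.size(path) == 0) {
    data.frame(pattern_id = character(), class = character(),
               pattern = character(), stringsAsFactors = FALSE)
  } else {
    read_tsv_table(path)
  }
  if (!nrow(df)) {
    return(data.frame(pattern_id = character(), class = character(),
                      pattern = character(), regex = character(),
                      stringsAsFactors = FALSE))
  }
  required <- c("pattern_id", "class", "pattern")
  if (!all(required %in% names(df))) {
    stop("motif config must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$pattern_id)) {
    stop("duplicate pattern_id in motif config: ",
         paste(unique(df$pattern_id[duplicated(df$pattern_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(df$class %in% MOTIF_CLASSES)) {
    stop("motif class must be one of ", paste(MOTIF_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  df$regex <- vapply(seq_len(nrow(df)), function(i) {
    compile_prosite(df$pattern[i], df$pattern_id[i])
  }, character(1))
  df
}

#' Path of the shipped placeholder motif config
#'
#' The 8 AHL-binding and 3 non-AHL-binding motifs of the source literature
#' are cited, not printed, in the survey this package implements; the shipped
#' file therefore contains clearly-marked placeholder patterns (used by the
#' synthetic-genome generator).  Transcribe the real motifs from the cited
#' references into a copy of this file before production use.
#'
#' @return file path.
#' @export
default_motif_config <- function() {
  system.file("extdata", "motifs_default.tsv", package = "luxrsolo",
              mustWork = TRUE)
}

#' Scan one protein for AHL / non-AHL motifs
#'
#' A pattern matches if its expression occurs at any position.  The label is
#' AHL when only AHL-class patterns match, NON_AHL when only non-AHL-class
#' patterns match, BOTH when both classes match (flagged with a warning, as
#' the two classes are expected to be mutually exclusive), NEITHER when
#' nothing matches.
#'
#' @param protein_seq amino-acid string.
#' @param patterns pattern frame from [parse_motif_config()].
#' @return list: `label`, `matched` (pattern ids).
#' @export
scan_motifs <- function(protein_seq, patterns) {
  assert_protein(protein_seq)
  hit <- vapply(patterns$regex, function(re) grepl(re, protein_seq,
                                                   perl = TRUE), logical(1))
  matched <- patterns$pattern_id[hit]
  classes <- unique(patterns$class[hit])
  label <- if (!length(matched)) {
    "NEITHER"
  } else if (setequal(classes, "AHL")) {
    "AHL"
  } else if (setequal(classes, "NON_AHL")) {
    "NON_AHL"
  } else {
    warning("sequence matches both AHL and non-AHL motifs (",
            paste(matched, collapse = ","), ")", call. = FALSE)
    "BOTH"
  }
  list(label = label, matched = matched)
}

#' Motif labels for a table of proteins
#'
#' @param genes gene table (uses `gene_id`, `protein_seq`).
#' @param patterns pattern frame from [parse_motif_config()].
#' @return data frame `gene_id`, `label`, `matched` (comma-separated).
#' @export
motif_labels <- function(genes, patterns) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    if (is.na(genes$protein_seq[i])) {
      return(data.frame(gene_id = genes$gene_id[i], label = "NEITHER",
                        matched = "", stringsAsFactors = FALSE))
    }
    r <- scan_motifs(genes$protein_seq[i], patterns)
    data.frame(gene_id = genes$gene_id[i], label = r$label,
               matched = paste(r$matched, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), label = character(),
                      matched = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Consensus motif class of a clade
#'
#' AHL when every member is AHL, NON_AHL when every member is NON_AHL,
#' NEITHER when every member is NEITHER, MIXED otherwise.
#'
#' @param labels character vector of member labels.
#' @return `"AHL"`, `"NON_AHL"`, `"NEITHER"` or `"MIXED"`.
#' @export
clade_motif_consensus <- function(labels) {
  if (!length(labels)) stop("empty clade", call. = FALSE)
  u <- unique(labels)
  if (identical(u, "AHL")) "AHL"
  else if (identical(u, "NON_AHL")) "NON_AHL"
  else if (identical(u, "NEITHER")) "NEITHER"
  else "MIXED"
}
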