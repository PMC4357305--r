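# Dual-domain LuxR detection: a gene is called LUXR only if it carries both
# an autoinducer-binding (AUTOIND) and a GerE-type DNA-binding (GERE) domain,
# in that N-to-C order, and its length falls in the configured LuxR range.

QS_DOMAIN_KINDS <- c("AUTOIND", "GERE", "SYNTHASE", "RSAM", "RSAL")

QS_ROLES <- c("LUXR", "LUXI", "RSAM", "RSAL", "NONE")

DIAG_CODES <- c("MISSING_AUTOIND", "MISSING_GERE", "WRONG_ORDER",
                "LENGTH_OUT_OF_RANGE", "BELOW_THRESHOLD", "UNTRANSLATABLE")

#' Consensus segments recognised by the consensus-pattern backend
#'
#' Fixed arbitrary amino-acid strings, one per domain kind, shared between the
#' built-in consensus-pattern detection backend and the synthetic-genome
#' generator.  Lowercase `x` marks wildcard positions that match any residue
#' (the generator plants cysteines there).  These segments are deliberately
#' *not* PFAM consensi: they exist so that detection, topology and downstream
#' statistics can be exercised end-to-end without profile databases.  For real
#' genomes use the `profile-hmm` backend with PF03472/PF00196/PF00765 profiles.
#'
#' @return named list of consensus strings for AUTOIND, GERE, SYNTHASE, RSAM
#'   and RSAL.
#' @export
qs_consensus_segments <- function() {
  list(
    AUTOIND  = "KDLFTGAxHEIVRDLxNPQSTYAxGDFEIKLxMHRSTVAxDGEILNPxQRSTYADFGIKL",
    GERE     = "ADEFGHIKLMNxPQRSTVYADEFGHxIKLMNPQRSTVYAD",
    SYNTHASE = "FDGHKLRTYEAIMNPSVDQGFHKLERTYAMINPSVQDGHFKLRTE",
    RSAM     = "MDEHGIKFLNPARSTVYQDGEHIFKLMNPRSTVYA",
    RSAL     = "YTSRQPNMLKIFHGEDAYTSRQPNMLKIFHGEDAV"
  )
}

#' Detection configuration
#'
#' @param backend `"consensus-pattern"` (built-in deterministic matcher, the
#'   default; used by tests and synthetic data) or `"profile-hmm"` (delegates
#'   to the external HMMER `hmmsearch` binary given profile files).
#' @param evalue_cutoff E-value threshold per domain hit (profile-hmm backend;
#'   the consensus backend reports E-value 0 for every accepted match).
#' @param luxr_length_range accepted LuxR protein length in residues.
#'   Canonical members (TraR, LuxR, QscR) fall around 210--260 aa; the default
#'   150--300 leaves margin for family spread.
#' @param luxi_length_range accepted LuxI (AHL synthase) length in residues.
#' @param max_mismatch mismatch tolerance of the consensus-pattern matcher at
#'   non-wildcard positions.
#' @param consensus named list of consensus segments (consensus backend).
#' @param profiles named character vector of HMMER3 profile file paths, names
#'   in `QS_DOMAIN_KINDS` (profile-hmm backend).
#' @param rsam_fallback when no rsaM/rsaL domain evidence is available, fall
#'   back to a case-insensitive product-text match on "rsam"/"rsal".
#' @return object of class `detection_config`.
#' @export
detection_config <- function(backend = c("consensus-pattern", "profile-hmm"),
                             evalue_cutoff = 1e-5,
                             luxr_length_range = c(150L, 300L),
                             luxi_length_range = c(120L, 250L),
                             max_mismatch = 2L,
                             consensus = qs_consensus_segments(),
                             profiles = NULL,
                             rsam_fallback = TRUE) {
  backend <- match.arg(backend)
  stopifnot(evalue_cutoff > 0,
            length(luxr_length_range) == 2L,
            luxr_length_range[1] <= luxr_length_range[2],
            length(luxi_length_range) == 2L,
            luxi_length_range[1] <= luxi_length_range[2],
            max_mismatch >= 0L)
  if (backend == "profile-hmm") {
    if (is.null(profiles) || is.null(names(profiles))) {
      stop("profile-hmm backend requires a named vector of profile paths",
           call. = FALSE)
    }
    missing <- !file.exists(profiles)
    if (any(missing)) {
      stop("profile file(s) not found: ",
           paste(profiles[missing], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(backend = backend,
         evalue_cutoff = evalue_cutoff,
         luxr_length_range = as.integer(luxr_length_range),
         luxi_length_range = as.integer(luxi_length_range),
         max_mismatch = as.integer(max_mismatch),
         consensus = consensus,
         profiles = profiles,
         rsam_fallback = isTRUE(rsam_fallback)),
    class = "detection_config")
}

empty_hits <- function() {
  data.frame(domain_kind = character(), q_start = integer(),
             q_end = integer(), score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

# Sliding-window consensus match allowing <= k mismatches at non-wildcard
# positions.  Overlapping candidate windows of the same kind are collapsed,
# best window (fewest mismatches, then leftmost) first.
consensus_scan <- function(seq_chars, cons, kind, max_mismatch) {
  cons_chars <- strsplit(cons, "")[[1]]
  m <- length(cons_chars)
  L <- length(seq_chars)
  if (L < m) return(empty_hits())
  fixed <- which(cons_chars != "x")
  cfix <- cons_chars[fixed]
  offsets <- seq_len(L - m + 1L)
  mism <- vapply(offsets, function(o) sum(seq_chars[o + fixed - 1L] != cfix),
                 integer(1))
  ok <- which(mism <= max_mismatch)
  if (!length(ok)) return(empty_hits())
  ok <- ok[order(mism[ok], ok)]
  kept <- integer()
  for (o in ok) {
    if (!any(abs(kept - o) < m)) kept <- c(kept, o)
  }
  kept <- sort(kept)
  data.frame(domain_kind = kind,
             q_start = kept,
             q_end = kept + m - 1L,
             score = as.numeric(length(fixed) - mism[kept]),
             evalue = 0,
             stringsAsFactors = FALSE)
}

#' Find domain hits in a protein sequence
#'
#' @param protein_seq amino-acid string (20 standard letters plus X).
#' @param config a [detection_config()].
#' @return data frame of hits (`domain_kind`, `q_start`, `q_end`, `score`,
#'   `evalue`), sorted by `q_start`; only hits with `evalue <=` the cutoff are
#'   returned.  Attribute `filtered_kinds` names domain kinds whose candidate
#'   hits were all rejected by the E-value cutoff.
#' @export
detect_domains <- function(protein_seq, config = detection_config()) {
  assert_protein(protein_seq)
  hits <- switch(config$backend,
    "consensus-pattern" = {
      sc <- strsplit(protein_seq, "")[[1]]
      do.call(rbind, lapply(names(config$consensus), function(kind) {
        consensus_scan(sc, config$consensus[[kind]], kind,
                       config$max_mismatch)
      }))
    },
    "profile-hmm" = hmmsearch_domains(protein_seq, config),
    stop("unknown detection backend: ", config$backend, call. = FALSE)
  )
  if (is.null(hits) || !nrow(hits)) return(empty_hits())
  keep <- hits$evalue <= config$evalue_cutoff
  filtered_kinds <- setdiff(unique(hits$domain_kind[!keep]),
                            unique(hits$domain_kind[keep]))
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$q_start, hits$domain_kind), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "filtered_kinds") <- filtered_kinds
  hits
}

# External HMMER driver: one hmmsearch run per profile, domain table parsed
# back into the uniform hit frame.  Alignment (not envelope) coordinates are
# reported, with the per-domain independent E-value.
hmmsearch_domains <- function(protein_seq, config) {
  exe <- Sys.which("hmmsearch")
  if (!nzchar(exe)) stop("hmmsearch binary not found on PATH", call. = FALSE)
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(c(">query", protein_seq), fa)
  out <- lapply(names(config$profiles), function(kind) {
    tbl <- tempfile(fileext = ".domtbl")
    on.exit(unlink(tbl), add = TRUE)
    status <- system2(exe, c("--domtblout", shQuote(tbl), "--cpu", "1",
                             shQuote(config$profiles[[kind]]), shQuote(fa)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0) stop("hmmsearch failed for profile ", kind, call. = FALSE)
    lines <- readLines(tbl)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) return(empty_hits())
    f <- strsplit(trimws(lines), "[[:space:]]+")
    data.frame(domain_kind = kind,
               q_start = vapply(f, function(x) as.integer(x[18]), integer(1)),
               q_end = vapply(f, function(x) as.integer(x[19]), integer(1)),
               score = vapply(f, function(x) as.numeric(x[14]), numeric(1)),
               evalue = vapply(f, function(x) as.numeric(x[13]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

best_hit <- function(hits, kind) {
  h <- hits[hits$domain_kind == kind, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h[order(-h$score, h$q_start), , drop = FALSE][1, ]
}

#' Classify one gene's quorum-sensing role
#'
#' Applies the dual-domain rule: LUXR requires at least one AUTOIND and one
#' GERE hit, the autoinducer-binding domain N-terminal to the DNA-binding
#' domain (compared by `q_start` of the best-scoring hit of each kind), and a
#' protein length within the configured LuxR range.  LUXI requires a SYNTHASE
#' hit plus the LuxI length window; rsaM/rsaL are called from their
#' single-domain hits, with an optional product-text fallback.  Everything
#' else is NONE, with diagnostics listing every failed LuxR condition.
#'
#' @param gene a gene record (list or one-row data frame with `gene_id`,
#'   `protein_seq` and optionally `product`).
#' @param hits hit frame from [detect_domains()] for this gene's protein.
#' @param config a [detection_config()].
#' @return list of class `qs_detection` with `gene_id`, `role`, `hits`,
#'   `diagnostics`.
#' @export
classify_gene <- function(gene, hits, config = detection_config()) {
  plen <- if (is.na(gene$protein_seq %||% NA)) NA_integer_ else
    nchar(gene$protein_seq)
  diag <- character()
  role <- "NONE"
  if (is.na(plen)) {
    diag <- "UNTRANSLATABLE"
  } else {
    au <- best_hit(hits, "AUTOIND")
    ge <- best_hit(hits, "GERE")
    len_ok <- plen >= config$luxr_length_range[1] &&
      plen <= config$luxr_length_range[2]
    order_ok <- !is.null(au) && !is.null(ge) && au$q_start < ge$q_start
    if (!is.null(au) && !is.null(ge) && order_ok && len_ok) {
      role <- "LUXR"
    } else {
      if (is.null(au)) diag <- c(diag, "MISSING_AUTOIND")
      if (is.null(ge)) diag <- c(diag, "MISSING_GERE")
      if (!is.null(au) && !is.null(ge) && !order_ok) {
        diag <- c(diag, "WRONG_ORDER")
      }
      if (!len_ok) diag <- c(diag, "LENGTH_OUT_OF_RANGE")
      sy <- best_hit(hits, "SYNTHASE")
      luxi_len_ok <- plen >= config$luxi_length_range[1] &&
        plen <= config$luxi_length_range[2]
      if (!is.null(sy) && luxi_len_ok) {
        role <- "LUXI"
      } else if (!is.null(best_hit(hits, "RSAM"))) {
        role <- "RSAM"
      } else if (!is.null(best_hit(hits, "RSAL"))) {
        role <- "RSAL"
      } else if (config$rsam_fallback && !is.null(gene$product) &&
                 !is.na(gene$product)) {
        if (grepl("rsam", gene$product, ignore.case = TRUE)) role <- "RSAM"
        if (grepl("rsal", gene$product, ignore.case = TRUE)) role <- "RSAL"
      }
      fk <- attr(hits, "filtered_kinds")
      if (role == "NONE" && length(fk)) diag <- c(diag, "BELOW_THRESHOLD")
    }
  }
  if (role != "NONE") diag <- character()
  structure(list(gene_id = gene$gene_id, role = role, hits = hits,
                 diagnostics = diag),
            class = "qs_detection")
}

#' Scan every gene of a genome for quorum-sensing roles
#'
#' Runs [detect_domains()] + [classify_gene()] over all annotated genes.
#' Genes flagged untranslatable (no protein sequence) are excluded from domain
#' detection and reported with role NONE and diagnostic UNTRANSLATABLE.
#'
#' @param genome a `qs_genome` from [read_annotated_genome()] or
#'   [generate_synthetic_genomes()].
#' @param config a [detection_config()].
#' @return data frame with one row per gene: `gene_id`, `contig_id`, `role`,
#'   `diagnostics` (comma-separated), `n_hits`, and the best-hit spans
#'   `au_start`, `au_end`, `gere_start`, `gere_end` (NA when absent).
#' @export
qs_scan_genome <- function(genome, config = detection_config()) {
  rows <- lapply(genome$contigs, function(ctg) {
    genes <- ctg$genes
    if (!nrow(genes)) return(NULL)
    out <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      hits <- if (is.na(g$protein_seq)) empty_hits() else
        detect_domains(g$protein_seq, config)
      det <- classify_gene(g, hits, config)
      au <- best_hit(hits, "AUTOIND")
      ge <- best_hit(hits, "GERE")
      data.frame(gene_id = g$gene_id, contig_id = ctg$contig_id,
                 role = det$role,
                 diagnostics = paste(det$diagnostics, collapse = ","),
                 n_hits = nrow(hits),
                 au_start = if (is.null(au)) NA_integer_ else au$q_start,
                 au_end = if (is.null(au)) NA_integer_ else au$q_end,
                 gere_start = if (is.null(ge)) NA_integer_ else ge$q_start,
                 gere_end = if (is.null(ge)) NA_integer_ else ge$q_end,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), contig_id = character(),
                      role = character(), diagnostics = character(),
                      n_hits = integer(), au_start = integer(),
                      au_end = integer(), gere_start = integer(),
                      gere_end = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
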