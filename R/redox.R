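# Cysteine statistics and the TraR-template disulfide screen.  Conserved
# cysteines of a clade are mapped by global alignment onto a template
# structure (the TraR/AHL/DNA co-crystal, PDB 1H0M, in the original survey)
# and pairs whose C-alpha atoms lie within disulfide range are reported.

#' Cysteine profile of one protein
#'
#' Counts cysteines overall and inside the autoinducer-binding and
#' DNA-binding domain spans (best-scoring hit per kind).
#'
#' @param protein_seq amino-acid string.
#' @param hits hit frame from [detect_domains()].
#' @return list of class `cys_profile`: `total_cys`, `autoind_cys`,
#'   `gere_cys`, `other_cys` (total = autoind + gere + other when the spans
#'   do not overlap).
#' @export
cys_profile <- function(protein_seq, hits = empty_hits()) {
  chars <- strsplit(protein_seq, "")[[1]]
  is_c <- chars == "C"
  span_count <- function(kind) {
    h <- best_hit(hits, kind)
    if (is.null(h)) return(0L)
    sum(is_c[seq(h$q_start, h$q_end)])
  }
  total <- sum(is_c)
  au <- span_count("AUTOIND")
  ge <- span_count("GERE")
  structure(list(total_cys = total, autoind_cys = au, gere_cys = ge,
                 other_cys = total - au - ge),
            class = "cys_profile")
}

#' Per-clade cysteine statistics
#'
#' @param total_cys integer vector of per-member total cysteine counts
#'   (>= 1 member).
#' @return list of class `clade_cys_stats`: `min_cys`, `max_cys`, `mean_cys`
#'   (2-decimal precision) and `formatted` ("min--max, mean" with an en dash,
#'   trailing zeros dropped, e.g. `"4–4, 4"` for a constant clade of 4).
#' @export
clade_cys_stats <- function(total_cys) {
  if (!length(total_cys)) stop("empty clade", call. = FALSE)
  mn <- min(total_cys)
  mx <- max(total_cys)
  me <- round(mean(total_cys), 2)
  structure(list(min_cys = mn, max_cys = mx, mean_cys = me,
                 formatted = format_cys_stats(mn, mx, me)),
            class = "clade_cys_stats")
}

format_cys_stats <- function(mn, mx, me) {
  mtxt <- sub("0+$", "", sprintf("%.2f", me))
  mtxt <- sub("\\.$", "", mtxt)
  paste0(mn, "–", mx, ", ", mtxt)
}

#' Read a C-alpha template structure from a PDB file
#'
#' Parses ATOM records, keeps C-alpha atoms only (first altloc wins,
#' duplicate residue numbers keep the first occurrence with a warning),
#' chains kept separate.
#'
#' @param path PDB file path.
#' @param source_id identifier recorded on the object (defaults to the file
#'   base name).
#' @return object of class `template_structure`: data frame `atoms` with
#'   `chain`, `resno`, `resid` (one-letter), `x`, `y`, `z`, plus `source_id`.
#' @export
read_template <- function(path, source_id = NULL) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("no C-alpha ATOM records in ", path, call. = FALSE)
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]
  # first altloc / first duplicate wins
  key <- paste(at$chain, at$resno)
  if (anyDuplicated(key)) {
    warning("duplicate C-alpha records (altloc or repeated residue); ",
            "keeping first occurrence", call. = FALSE)
    at <- at[!duplicated(key), , drop = FALSE]
  }
  stopifnot(all(is.finite(at$x)), all(is.finite(at$y)), all(is.finite(at$z)))
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resid = bio3d::aa321(at$resid),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(atoms = atoms, source_id = source_id),
            class = "template_structure")
}

#' One-letter sequence and residue numbering of a template chain
#' @param template a `template_structure`.
#' @param chain chain id (default the first chain).
#' @return list: `seq` (string), `resno` (integer vector, one per residue).
#' @export
template_chain_seq <- function(template, chain = NULL) {
  at <- template$atoms
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("chain not present: ", chain, call. = FALSE)
  res <- at$resid
  res[is.na(res) | !(res %in% AA_LETTERS)] <- "X"
  list(seq = paste(res, collapse = ""), resno = at$resno)
}

#' Map query residue positions onto template numbering
#'
#' Globally aligns the query to the template chain sequence; query positions
#' aligned to a template residue map to that residue's number, gap-aligned
#' positions map to nothing.  The mapping is strictly increasing over mapped
#' positions.
#'
#' @param query_seq protein sequence.
#' @param template a `template_structure`.
#' @param chain template chain id (default first chain).
#' @param scoring an [align_scoring()].
#' @return integer vector of length `nchar(query_seq)`: template residue
#'   number per query position, `NA` where unaligned.
#' @export
map_positions_to_template <- function(query_seq, template, chain = NULL,
                                      scoring = align_scoring()) {
  tpl <- template_chain_seq(template, chain)
  al <- pairwise_align(query_seq, tpl$seq, scoring)
  qa <- strsplit(al$aligned_a, "")[[1]]
  ta <- strsplit(al$aligned_b, "")[[1]]
  map <- rep(NA_integer_, nchar(query_seq))
  qi <- 0L; ti <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (ta[k] != "-") ti <- ti + 1L
    if (qa[k] != "-" && ta[k] != "-") map[qi] <- tpl$resno[ti]
  }
  map
}

#' Screen template positions for potential disulfide bridges
#'
#' Reports every unordered pair of the given template residues whose
#' C-alpha--C-alpha Euclidean distance is within the cutoff, sorted by
#' distance.  The default cutoff of 6.8 A is the upper end of distances seen
#' in disulfide surveys; genuine bridges typically sit near 4-6 A.
#'
#' @param positions template residue numbers (duplicates collapsed;
#'   positions absent from the chain are skipped with a warning).
#' @param template a `template_structure`.
#' @param chain chain id (default first chain).
#' @param cutoff maximum C-alpha distance in Angstrom.
#' @param clade_id optional clade label carried into the output.
#' @return data frame `clade_id`, `template_pos_1`, `template_pos_2`,
#'   `ca_distance` (rounded to 1 decimal), `chain`.
#' @export
predict_disulfides <- function(positions, template, chain = NULL,
                               cutoff = 6.8, clade_id = NA_character_) {
  at <- template$atoms
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  positions <- unique(positions)
  missing <- setdiff(positions, at$resno)
  if (length(missing)) {
    warning("position(s) absent from chain ", chain, ": ",
            paste(missing, collapse = ", "), call. = FALSE)
    positions <- setdiff(positions, missing)
  }
  empty <- data.frame(clade_id = character(), template_pos_1 = integer(),
                      template_pos_2 = integer(), ca_distance = numeric(),
                      chain = character(), stringsAsFactors = FALSE)
  if (length(positions) < 2) return(empty)
  co <- at[match(positions, at$resno), c("x", "y", "z")]
  pairs <- utils::combn(seq_along(positions), 2)
  dist <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sqrt(sum((co[i, ] - co[j, ])^2))
  }, numeric(1))
  keep <- which(dist <= cutoff)
  if (!length(keep)) return(empty)
  out <- data.frame(clade_id = clade_id,
                    template_pos_1 = positions[pairs[1, keep]],
                    template_pos_2 = positions[pairs[2, keep]],
                    ca_distance = round(dist[keep], 1),
                    chain = chain, stringsAsFactors = FALSE)
  out <- out[order(out$ca_distance, out$template_pos_1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic C-alpha template for offline testing
#'
#' Builds a small helix-like C-alpha trace as a `template_structure`.  This
#' is a synthetic stand-in used by examples and tests; it is not derived from
#' any crystal structure.  For the real TraR-template screen, point
#' [read_template()] at a local copy of PDB entry 1H0M.
#'
#' @param n_res residues per chain.
#' @param chains chain ids.
#' @param seq optional sequence (recycled/truncated to `n_res`); defaults to
#'   a repeating pattern with cysteines every 10th residue.
#' @return a `template_structure` with `source_id = "synthetic"`.
#' @export
synthetic_template <- function(n_res = 60, chains = "A", seq = NULL) {
  if (is.null(seq)) {
    base <- rep("A", n_res)
    base[seq(5, n_res, by = 10)] <- "C"
    seq <- paste(base, collapse = "")
  }
  res <- strsplit(seq, "")[[1]][seq_len(n_res)]
  atoms <- do.call(rbind, lapply(seq_along(chains), function(ci) {
    t <- seq_len(n_res)
    # idealised alpha-helix: rise 1.5 A per residue, radius 2.3 A, 100 deg turn
    ang <- (t - 1) * 100 * pi / 180
    data.frame(chain = chains[ci], resno = t, resid = res,
               x = 2.3 * cos(ang) + 30 * (ci - 1),
               y = 2.3 * sin(ang),
               z = 1.5 * t, stringsAsFactors = FALSE)
  }))
  structure(list(atoms = atoms, source_id = "synthetic"),
            class = "template_structure")
}
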