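# Chromosomal-neighborhood topology grammar for validated luxR genes.
# Circuit labels (RI_*, RMI, RLI, RXMI) take precedence over twin-luxR
# arrangements, which take precedence over plain SOLO; twins are themselves a
# subtype of solos (no luxI within range).

TOPOLOGY_LABELS <- c("RI_TANDEM", "RI_CONVERGENT", "RI_DIVERGENT", "RMI",
                     "RLI", "RXMI", "TWIN_RR_TANDEM", "TWIN_RR_DIVERGENT",
                     "SOLO")

SOLO_LABELS <- c("TWIN_RR_TANDEM", "TWIN_RR_DIVERGENT", "SOLO")

#' Topology distance thresholds
#'
#' A luxI within `simple_distance_bp` defines the simple circuit classes
#' (RI/RMI/RLI); `rxmi_distance_bp` is the wider window allowed for RXMI
#' (an extra gene X plus rsaM between luxR and luxI); `twin_distance_bp`
#' bounds the twin-luxR search.  "Within" is read as inclusive: a gap of
#' exactly `simple_distance_bp` is still a circuit, one bp more is not.
#'
#' @param simple_distance_bp default 3000.
#' @param rxmi_distance_bp default 3400.
#' @param twin_distance_bp default 3000.
#' @return object of class `topology_config`.
#' @export
topology_config <- function(simple_distance_bp = 3000L,
                            rxmi_distance_bp = 3400L,
                            twin_distance_bp = 3000L) {
  stopifnot(simple_distance_bp > 0, rxmi_distance_bp > 0,
            twin_distance_bp > 0)
  structure(list(simple_distance_bp = as.integer(simple_distance_bp),
                 rxmi_distance_bp = as.integer(rxmi_distance_bp),
                 twin_distance_bp = as.integer(twin_distance_bp)),
            class = "topology_config")
}

#' Intergenic gap between two genes
#'
#' Distance between nearest gene edges: `max(0, larger start - smaller end
#' - 1)`; 0 for overlapping or abutting genes.  Symmetric.  Genes must share
#' a contig.
#'
#' @param a,b gene records (rows of a gene table).
#' @return gap in base pairs.
#' @export
gene_gap <- function(a, b) {
  if (a$contig_id != b$contig_id) {
    stop("genes on different contigs are not comparable", call. = FALSE)
  }
  if (a$start > b$start || (a$start == b$start && a$end > b$end)) {
    tmp <- a; a <- b; b <- tmp
  }
  max(0L, b$start - a$end - 1L)
}

#' Relative orientation of two genes on one contig
#'
#' TANDEM when both genes lie on the same strand.  For opposite strands the
#' pair is CONVERGENT when the genes point toward each other (the + strand
#' gene lies left of the - strand gene) and DIVERGENT when they point apart.
#'
#' @param r,partner gene records on the same contig.
#' @return `"TANDEM"`, `"CONVERGENT"` or `"DIVERGENT"`.
#' @export
relative_orientation <- function(r, partner) {
  if (r$strand == partner$strand) return("TANDEM")
  plus <- if (r$strand == "+") r else partner
  minus <- if (r$strand == "-") r else partner
  if (plus$start <= minus$start) "CONVERGENT" else "DIVERGENT"
}

# genes of `ctg` lying strictly between two non-overlapping genes
genes_between <- function(ctg_genes, left, right) {
  inner_lo <- min(left$end, right$end)
  inner_hi <- max(left$start, right$start)
  sel <- ctg_genes$start > inner_lo & ctg_genes$end < inner_hi &
    !(ctg_genes$gene_id %in% c(left$gene_id, right$gene_id))
  ctg_genes[sel, , drop = FALSE]
}

role_of <- function(detections, id) {
  r <- detections$role[detections$gene_id == id]
  if (!length(r)) "NONE" else r[1]
}

#' Classify the neighborhood of one validated luxR gene
#'
#' Decision procedure, in precedence order: (1) the nearest LUXI on the same
#' contig within the RXMI window defines a circuit — RI (suffix from
#' [relative_orientation()]) when the gap is within the simple window with no
#' annotated gene between, RMI/RLI when exactly one rsaM/rsaL lies between,
#' RXMI when the intervening genes are one rsaM plus one other gene (either
#' internal order) within the RXMI window; (2) otherwise the nearest other
#' LUXR within the twin window in tandem or divergent orientation makes a
#' twin-luxR arrangement (convergent twins are not a class: such a pair falls
#' through to SOLO with a warning); (3) otherwise SOLO.  `edge_flag` is set
#' when the luxR lies within the simple search distance of a contig end — the
#' honesty mechanism for draft assemblies, where a partner may be missing
#' from the contig rather than from the genome.
#'
#' @param genome a `qs_genome`.
#' @param luxr gene record of a gene detected as LUXR.
#' @param detections detection frame from [qs_scan_genome()] (or any frame
#'   with `gene_id` and `role`).
#' @param config a [topology_config()].
#' @return one-row data frame: `luxr_gene_id`, `label`, `partner_ids`
#'   (comma-separated), `gap_bp`, `edge_flag`, `is_solo`.
#' @export
classify_neighborhood <- function(genome, luxr, detections,
                                  config = topology_config()) {
  ctg <- genome$contigs[[luxr$contig_id]]
  genes <- ctg$genes
  others <- genes[genes$gene_id != luxr$gene_id, , drop = FALSE]
  roles <- vapply(others$gene_id, role_of, "", detections = detections)
  gaps <- if (nrow(others)) {
    vapply(seq_len(nrow(others)), function(i) gene_gap(luxr, others[i, ]),
           integer(1))
  } else integer()

  label <- "SOLO"
  partner_ids <- character()
  gap_bp <- NA_integer_

  # (1) circuits: nearest luxI within the RXMI window
  luxi_idx <- which(roles == "LUXI" & gaps <= config$rxmi_distance_bp)
  if (length(luxi_idx)) {
    luxi_idx <- luxi_idx[order(gaps[luxi_idx])]
    for (i in luxi_idx) {
      luxi <- others[i, ]
      g <- gaps[i]
      between <- genes_between(genes, luxr, luxi)
      broles <- vapply(between$gene_id, role_of, "", detections = detections)
      if (g <= config$simple_distance_bp && nrow(between) == 0L) {
        label <- paste0("RI_", relative_orientation(luxr, luxi))
        partner_ids <- luxi$gene_id
        gap_bp <- g
        break
      }
      if (g <= config$simple_distance_bp && nrow(between) == 1L &&
          broles[1] == "RSAM") {
        label <- "RMI"
        partner_ids <- c(between$gene_id, luxi$gene_id)
        gap_bp <- g
        break
      }
      if (g <= config$simple_distance_bp && nrow(between) == 1L &&
          broles[1] == "RSAL") {
        label <- "RLI"
        partner_ids <- c(between$gene_id, luxi$gene_id)
        gap_bp <- g
        break
      }
      if (nrow(between) == 2L && sum(broles == "RSAM") == 1L) {
        label <- "RXMI"
        partner_ids <- c(between$gene_id, luxi$gene_id)
        gap_bp <- g
        break
      }
    }
  }

  # (2) twins: nearest other luxR within the twin window
  if (label == "SOLO") {
    twin_idx <- which(roles == "LUXR" & gaps <= config$twin_distance_bp)
    if (length(twin_idx)) {
      i <- twin_idx[order(gaps[twin_idx])][1]
      ori <- relative_orientation(luxr, others[i, ])
      if (ori == "TANDEM") {
        label <- "TWIN_RR_TANDEM"
        partner_ids <- others$gene_id[i]
        gap_bp <- gaps[i]
      } else if (ori == "DIVERGENT") {
        label <- "TWIN_RR_DIVERGENT"
        partner_ids <- others$gene_id[i]
        gap_bp <- gaps[i]
      } else {
        warning("notable case: convergent adjacent luxR pair (",
                luxr$gene_id, ", ", others$gene_id[i],
                ") is not a twin class; classified SOLO", call. = FALSE)
      }
    }
  }

  edge_flag <- (luxr$start - 1L) < config$simple_distance_bp ||
    (ctg$length - luxr$end) < config$simple_distance_bp
  data.frame(luxr_gene_id = luxr$gene_id,
             label = label,
             partner_ids = paste(partner_ids, collapse = ","),
             gap_bp = gap_bp,
             edge_flag = edge_flag,
             is_solo = label %in% SOLO_LABELS,
             stringsAsFactors = FALSE)
}

#' Classify every validated luxR in a genome
#'
#' @param genome a `qs_genome`.
#' @param detections detection frame from [qs_scan_genome()].
#' @param config a [topology_config()].
#' @return data frame with one row per LUXR gene (see
#'   [classify_neighborhood()]) plus `contig_id` and `genome_id`.
#' @export
classify_topologies <- function(genome, detections,
                                config = topology_config()) {
  luxr_ids <- detections$gene_id[detections$role == "LUXR"]
  genes <- genome_genes(genome)
  rows <- lapply(luxr_ids, function(id) {
    g <- genes[genes$gene_id == id, , drop = FALSE][1, ]
    out <- classify_neighborhood(genome, g, detections, config)
    cbind(genome_id = genome$genome_id, contig_id = g$contig_id, out,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), contig_id = character(),
                      luxr_gene_id = character(), label = character(),
                      partner_ids = character(), gap_bp = integer(),
                      edge_flag = logical(), is_solo = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Census of topology assignments
#'
#' @param assignments frame from [classify_topologies()] (possibly
#'   row-bound over genomes).
#' @param genes optional gene table supplying `is_hypothetical` flags.
#' @param digits precision of the solo fraction, default 1.
#' @return list of class `census_summary`: `total_luxr`,
#'   `total_hypothetical`, per-label counts, `circuit_count`, `solo_count`
#'   (twins included), `twin_count`, `solo_fraction_percent` (`NA` for empty
#'   input), `hypothetical_solo`, `hypothetical_circuit`.
#' @export
census_summary <- function(assignments, genes = NULL, digits = 1) {
  n <- nrow(assignments)
  per_label <- vapply(TOPOLOGY_LABELS,
                      function(l) sum(assignments$label == l), integer(1))
  solo_count <- sum(assignments$is_solo)
  twin_count <- sum(assignments$label %in%
                      c("TWIN_RR_TANDEM", "TWIN_RR_DIVERGENT"))
  hyp <- function(sel) {
    if (is.null(genes) || !n) return(NA_integer_)
    ids <- assignments$luxr_gene_id[sel]
    sum(genes$is_hypothetical[genes$gene_id %in% ids])
  }
  structure(list(
    total_luxr = n,
    per_label = per_label,
    circuit_count = n - solo_count,
    solo_count = solo_count,
    twin_count = twin_count,
    solo_fraction_percent = if (n) round(100 * solo_count / n, digits)
                            else NA_real_,
    total_hypothetical = hyp(rep(TRUE, n)),
    hypothetical_solo = hyp(assignments$is_solo),
    hypothetical_circuit = hyp(!assignments$is_solo)),
    class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  cat("LuxR census\n")
  cat("  total luxR:      ", x$total_luxr,
      if (!is.na(x$total_hypothetical)) {
        paste0(" (", x$total_hypothetical, " hypothetical)")
      } else "", "\n", sep = "")
  cat("  circuit members: ", x$circuit_count, "\n", sep = "")
  cat("  solos:           ", x$solo_count, " (", x$twin_count,
      " in twin arrangements)\n", sep = "")
  cat("  solo fraction:   ",
      if (is.na(x$solo_fraction_percent)) "undefined (no luxR)"
      else paste0(x$solo_fraction_percent, "%"), "\n", sep = "")
  cat("  per label:\n")
  for (l in names(x$per_label)) {
    if (x$per_label[[l]] > 0) cat(sprintf("    %-18s %d\n", l, x$per_label[[l]]))
  }
  invisible(x)
}

#' Census summary as a one-row data frame (TSV-friendly)
#' @param x a `census_summary`.
#' @return data frame.
#' @export
census_as_table <- function(x) {
  cbind(data.frame(total_luxr = x$total_luxr,
                   circuit_count = x$circuit_count,
                   solo_count = x$solo_count,
                   twin_count = x$twin_count,
                   solo_fraction_percent = x$solo_fraction_percent,
                   total_hypothetical = x$total_hypothetical,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(x$per_label)))
}
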