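# End-to-end census pipeline.  Every stage is a pure function of its inputs
# and configuration, communicates via plain data frames, and has a TSV
# writer, so intermediate artifacts are inspectable and diffable the way a
# census audit needs them to be.

#' Run the full solo-luxR census on one genome
#'
#' Stages: domain scan and role classification; neighborhood topology for
#' every validated luxR; motif labels; cysteine profiles (domain spans from
#' the scan); optionally the similarity cladogram and clade extraction; the
#' census summary.
#'
#' @param genome a `qs_genome`.
#' @param detection a [detection_config()].
#' @param topology a [topology_config()].
#' @param patterns motif pattern frame from [parse_motif_config()].
#' @param tree build the neighbor-joining cladogram of LuxR proteins and
#'   extract clades (needs >= 3 luxR genes).
#' @param clade_max_distance within-clade path-distance threshold for
#'   [extract_clades()], in 1 - identity units.
#' @param scoring an [align_scoring()] for the cladogram.
#' @return list of class `qs_census`: `detections`, `assignments`, `motifs`,
#'   `cys`, `census`, and when `tree = TRUE` also `tree`, `clades`,
#'   `clade_stats` (per-clade motif consensus + cysteine statistics in the
#'   min–max/average layout).
#' @export
run_census <- function(genome,
                       detection = detection_config(),
                       topology = topology_config(),
                       patterns = parse_motif_config(),
                       tree = FALSE,
                       clade_max_distance = 0.3,
                       scoring = align_scoring()) {
  detections <- qs_scan_genome(genome, detection)
  assignments <- classify_topologies(genome, detections, topology)
  genes <- genome_genes(genome)
  luxr <- genes[genes$gene_id %in%
                  detections$gene_id[detections$role == "LUXR"], ,
                drop = FALSE]
  motifs <- motif_labels(luxr, patterns)
  cys <- luxr_cys_table(luxr, detections)
  out <- list(detections = detections, assignments = assignments,
              motifs = motifs, cys = cys,
              census = census_summary(assignments, genes))
  if (tree && nrow(luxr) >= 3) {
    seqs <- stats::setNames(luxr$protein_seq, luxr$gene_id)
    d <- identity_distance_matrix(seqs, scoring)
    nj <- build_nj_tree(d)
    clades <- extract_clades(nj, clade_max_distance)
    out$tree <- nj
    out$clades <- clades
    out$clade_stats <- clade_stats_table(clades, motifs, cys)
  }
  class(out) <- "qs_census"
  out
}

#' Cysteine profile table for LuxR genes
#'
#' @param luxr gene table of LUXR genes.
#' @param detections detection frame from [qs_scan_genome()] (provides the
#'   best-hit domain spans).
#' @return data frame `gene_id`, `total_cys`, `autoind_cys`, `gere_cys`,
#'   `other_cys`.
#' @export
luxr_cys_table <- function(luxr, detections) {
  rows <- lapply(seq_len(nrow(luxr)), function(i) {
    g <- luxr[i, ]
    d <- detections[detections$gene_id == g$gene_id, , drop = FALSE][1, ]
    hits <- empty_hits()
    if (!is.na(d$au_start)) {
      hits <- rbind(hits, data.frame(domain_kind = "AUTOIND",
                                     q_start = d$au_start, q_end = d$au_end,
                                     score = 1, evalue = 0))
    }
    if (!is.na(d$gere_start)) {
      hits <- rbind(hits, data.frame(domain_kind = "GERE",
                                     q_start = d$gere_start,
                                     q_end = d$gere_end,
                                     score = 1, evalue = 0))
    }
    p <- cys_profile(g$protein_seq, hits)
    data.frame(gene_id = g$gene_id, total_cys = p$total_cys,
               autoind_cys = p$autoind_cys, gere_cys = p$gere_cys,
               other_cys = p$other_cys, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), total_cys = integer(),
                      autoind_cys = integer(), gere_cys = integer(),
                      other_cys = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Per-clade motif consensus and cysteine statistics
#'
#' One row per clade in the layout of the survey's per-clade table: member
#' count, motif consensus class, and cysteine content as "min–max, average".
#'
#' @param clades list from [extract_clades()].
#' @param motifs motif frame from [motif_labels()].
#' @param cys cysteine frame from [luxr_cys_table()].
#' @return data frame `clade_id`, `n_members`, `motif_consensus`,
#'   `cys_min`, `cys_max`, `cys_mean`, `cys_content`.
#' @export
clade_stats_table <- function(clades, motifs, cys) {
  rows <- lapply(names(clades), function(cl) {
    ids <- clades[[cl]]
    labs <- motifs$label[match(ids, motifs$gene_id)]
    counts <- cys$total_cys[match(ids, cys$gene_id)]
    st <- clade_cys_stats(counts)
    data.frame(clade_id = cl, n_members = length(ids),
               motif_consensus = clade_motif_consensus(labs),
               cys_min = st$min_cys, cys_max = st$max_cys,
               cys_mean = st$mean_cys, cys_content = st$formatted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Disulfide screen for every clade against a template structure
#'
#' For each clade: center-star alignment of the members, conserved cysteine
#' columns, mapping of the clade's anchor sequence onto the template chain,
#' and the C-alpha distance screen over the mapped conserved-cysteine
#' positions.  Also reports whether each predicted pair lies inside the
#' autoinducer-binding domain span of the anchor sequence.
#'
#' @param clades list from [extract_clades()].
#' @param genes gene table with protein sequences.
#' @param detections detection frame (for domain spans of the anchors).
#' @param template a `template_structure`.
#' @param chain template chain id (default first).
#' @param cutoff C-alpha distance cutoff in Angstrom.
#' @param scoring an [align_scoring()].
#' @return data frame in the disulfide-report layout: `clade_id`,
#'   `template_pos_1`, `template_pos_2`, `ca_distance`, `chain`,
#'   `in_autoind_domain`.
#' @export
clade_disulfide_screen <- function(clades, genes, detections, template,
                                   chain = NULL, cutoff = 6.8,
                                   scoring = align_scoring()) {
  out <- lapply(names(clades), function(cl) {
    ids <- clades[[cl]]
    seqs <- stats::setNames(
      genes$protein_seq[match(ids, genes$gene_id)], ids)
    anchor_id <- ids[1]
    if (length(ids) >= 2) {
      msa <- center_star_msa(seqs, scoring)
      cols <- conserved_cys_columns(msa)
      # conserved columns -> residue indices of the anchor sequence
      anchor_aln <- strsplit(msa[[anchor_id]], "")[[1]]
      resmap <- cumsum(anchor_aln != "-")
      qpos <- resmap[cols][anchor_aln[cols] != "-"]
    } else {
      qpos <- which(strsplit(seqs[[1]], "")[[1]] == "C")
    }
    if (!length(qpos)) return(NULL)
    tmap <- map_positions_to_template(seqs[[anchor_id]], template, chain,
                                      scoring)
    tpos <- tmap[qpos]
    tpos <- tpos[!is.na(tpos)]
    if (length(tpos) < 2) return(NULL)
    pairs <- predict_disulfides(tpos, template, chain, cutoff,
                                clade_id = cl)
    if (!nrow(pairs)) return(NULL)
    d <- detections[detections$gene_id == anchor_id, , drop = FALSE][1, ]
    in_autoind <- function(tp) {
      if (is.na(d$au_start)) return(NA)
      q <- qpos[match(tp, tmap[qpos])]
      !is.na(q) && q >= d$au_start && q <= d$au_end
    }
    pairs$in_autoind_domain <- vapply(seq_len(nrow(pairs)), function(k) {
      isTRUE(in_autoind(pairs$template_pos_1[k])) &&
        isTRUE(in_autoind(pairs$template_pos_2[k]))
    }, logical(1))
    pairs
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(clade_id = character(), template_pos_1 = integer(),
                      template_pos_2 = integer(), ca_distance = numeric(),
                      chain = character(), in_autoind_domain = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Compare a pipeline run against a generator truth table
#'
#' The closed-loop check: per planted gene, detected role vs truth role;
#' per planted luxR, topology label, motif class and total cysteine count vs
#' truth.  Edge-flagged assignments are compared like any other (the default
#' synthetic set plants its edge case with a SOLO truth label).
#'
#' @param census a `qs_census` from [run_census()].
#' @param truth truth table from [generate_synthetic_genomes()].
#' @return list of mismatch counts: `role`, `topology`, `motif`, `cys`, and
#'   `total` (their sum).
#' @export
truth_mismatches <- function(census, truth) {
  det <- census$detections
  role_called <- det$role[match(truth$gene_id, det$gene_id)]
  role_mm <- sum(is.na(role_called) | role_called != truth$role)

  tl <- truth[!is.na(truth$topology_label), , drop = FALSE]
  asn <- census$assignments
  lab <- asn$label[match(tl$gene_id, asn$luxr_gene_id)]
  topo_mm <- sum(is.na(lab) | lab != tl$topology_label)

  tm <- truth[!is.na(truth$motif_class), , drop = FALSE]
  got <- census$motifs$label[match(tm$gene_id, census$motifs$gene_id)]
  motif_mm <- sum(is.na(got) | got != tm$motif_class)

  tc <- truth[!is.na(truth$cys_autoind), , drop = FALSE]
  cys <- census$cys
  idx <- match(tc$gene_id, cys$gene_id)
  cys_mm <- sum(is.na(idx) |
                  cys$total_cys[idx] != tc$cys_total |
                  cys$autoind_cys[idx] != tc$cys_autoind |
                  cys$gere_cys[idx] != tc$cys_gere |
                  cys$other_cys[idx] != tc$cys_other)

  list(role = role_mm, topology = topo_mm, motif = motif_mm, cys = cys_mm,
       total = role_mm + topo_mm + motif_mm + cys_mm)
}

#' Write the census stage outputs as TSV files
#'
#' @param census a `qs_census`.
#' @param out_dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_census_outputs <- function(census, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(detections = file.path(out_dir, "detections.tsv"),
             topology = file.path(out_dir, "topology.tsv"),
             motifs = file.path(out_dir, "motifs.tsv"),
             cys = file.path(out_dir, "cysteines.tsv"),
             census = file.path(out_dir, "census.tsv"))
  write_tsv_table(census$detections, paths[["detections"]])
  write_tsv_table(census$assignments, paths[["topology"]])
  write_tsv_table(census$motifs, paths[["motifs"]])
  write_tsv_table(census$cys, paths[["cys"]])
  write_tsv_table(census_as_table(census$census), paths[["census"]])
  if (!is.null(census$tree)) {
    tree_path <- file.path(out_dir, "luxr_tree.nwk")
    ape::write.tree(census$tree, tree_path)
    write_tsv_table(clades_as_table(census$clades),
                    file.path(out_dir, "clades.tsv"))
    write_tsv_table(census$clade_stats,
                    file.path(out_dir, "clade_stats.tsv"))
    paths <- c(paths, tree = tree_path)
  }
  invisible(paths)
}
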