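# Deterministic synthetic-genome generator.  Plants QS cassettes of every
# topology class, decoy genes for every failure mode of the dual-domain
# rule, motif instances and per-domain cysteine counts, and emits GFF3 +
# FASTA (nt and aa) + a machine-readable truth table.
#
# Two deliberate idealisations make planted truth exact by construction:
# random protein filler is drawn from an alphabet without C and W, so
# cysteine counts come only from planted cysteines and motif matches only
# from planted instances (every placeholder motif is W-anchored); and
# nucleotide sequences are back-translated with one fixed codon per amino
# acid, so the GFF3+FASTA and protein-FASTA routes are mutually consistent.

FILLER_AA <- strsplit("ADEFGHIKLMNPQRSTVY", "")[[1]]

CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Literal instances of the shipped placeholder motifs
#'
#' One instance per placeholder pattern in `motifs_default.tsv`; the
#' generator embeds these so motif truth is exact.
#' @return named character vector, names are pattern ids.
#' @export
motif_instances <- function() {
  c(ahl_p1 = "WAKDGFLR", ahl_p2 = "WETDALIR", ahl_p3 = "WGRENAFT",
    ahl_p4 = "WHIPEATG", ahl_p5 = "WKDAFNEL", ahl_p6 = "WLEGARDS",
    ahl_p7 = "WNDFTARA", ahl_p8 = "WPSAELGK",
    non_p1 = "WRTIADNE", non_p2 = "WSENAFKD", non_p3 = "WTGDLASR")
}

rand_aa <- function(n) paste(sample(FILLER_AA, n, replace = TRUE),
                             collapse = "")

# region-mask codes: F filler, K consensus fixed position, P protected
# (planted cysteine, motif instance, wildcard fill, leading M)
seg <- function(seq, code) {
  list(seq = seq, mask = strsplit(strrep(code, nchar(seq)), "")[[1]])
}

fill_consensus_seg <- function(cons, n_cys = 0L) {
  chars <- strsplit(cons, "")[[1]]
  xpos <- which(chars == "x")
  if (n_cys > length(xpos)) {
    stop("cannot plant ", n_cys, " cysteines: consensus has only ",
         length(xpos), " wildcard positions", call. = FALSE)
  }
  chars[xpos] <- "A"
  if (n_cys > 0) chars[xpos[seq_len(n_cys)]] <- "C"
  mask <- rep("K", length(chars))
  mask[xpos] <- "P"
  list(seq = paste(chars, collapse = ""), mask = mask)
}

#' Build one synthetic protein of a given kind
#'
#' Kinds: `LUXR` (autoinducer-binding consensus, then GerE consensus, with
#' planted cysteines and an optional motif instance in the inter-domain
#' linker), `LUXI`, `RSAM`, `RSAL`, `XGENE`, and the decoy classes
#' `GERE_ONLY`, `AUTOIND_ONLY`, `WRONG_ORDER` (both domains, reversed) and
#' `LENGTH_OUT` (valid architecture but 450 residues).  Filler is drawn
#' from the current RNG stream.  The returned string carries a `mask`
#' attribute classifying every position as filler (`F`), consensus fixed
#' (`K`) or protected (`P`: planted cysteines, motif instance, wildcard
#' fills, leading methionine) — the hook for controlled mutation.
#'
#' @param kind one of the kinds above.
#' @param autoind_cys,gere_cys cysteines planted at the wildcard positions
#'   of the respective consensus segment (LUXR only).
#' @param other_cys cysteines planted in the linker, outside both domains.
#' @param motif_id placeholder motif id to embed (see [motif_instances()]),
#'   or `NA` for none.
#' @param target_len total protein length.
#' @return amino-acid string with attribute `mask`.
#' @export
synthetic_protein <- function(kind, autoind_cys = 0L, gere_cys = 0L,
                              other_cys = 0L, motif_id = NA_character_,
                              target_len = NULL) {
  cons <- qs_consensus_segments()
  motif <- if (is.na(motif_id)) "" else unname(motif_instances()[motif_id])
  assemble <- function(segs, total) {
    used <- sum(vapply(segs, function(s) nchar(s$seq), integer(1))) + 1L
    if (total <= used) stop("target_len too short for ", kind, call. = FALSE)
    segs <- c(list(seg("M", "P")), segs, list(seg(rand_aa(total - used), "F")))
    structure(paste(vapply(segs, `[[`, "", "seq"), collapse = ""),
              mask = unlist(lapply(segs, `[[`, "mask")))
  }
  switch(kind,
    LUXR = {
      if (is.null(target_len)) target_len <- 220L
      linker <- c(list(seg(rand_aa(4), "F")),
                  if (nzchar(motif)) list(seg(motif, "P")),
                  if (other_cys > 0) {
                    list(seg(strrep("C", other_cys), "P"))
                  },
                  list(seg(rand_aa(3), "F")))
      assemble(c(list(seg(rand_aa(10), "F"),
                      fill_consensus_seg(cons$AUTOIND, autoind_cys)),
                 linker,
                 list(fill_consensus_seg(cons$GERE, gere_cys))),
               target_len)
    },
    LUXI = assemble(list(seg(rand_aa(10), "F"),
                         fill_consensus_seg(cons$SYNTHASE)),
                    target_len %||% 150L),
    RSAM = assemble(list(seg(rand_aa(5), "F"),
                         fill_consensus_seg(cons$RSAM)),
                    target_len %||% 100L),
    RSAL = assemble(list(seg(rand_aa(5), "F"),
                         fill_consensus_seg(cons$RSAL)),
                    target_len %||% 95L),
    XGENE = assemble(list(), target_len %||% 100L),
    GERE_ONLY = assemble(list(seg(rand_aa(40), "F"),
                              fill_consensus_seg(cons$GERE)),
                         target_len %||% 200L),
    AUTOIND_ONLY = assemble(list(seg(rand_aa(10), "F"),
                                 fill_consensus_seg(cons$AUTOIND)),
                            target_len %||% 200L),
    WRONG_ORDER = assemble(list(seg(rand_aa(10), "F"),
                                fill_consensus_seg(cons$GERE),
                                seg(rand_aa(10), "F"),
                                fill_consensus_seg(cons$AUTOIND)),
                           target_len %||% 240L),
    LENGTH_OUT = assemble(list(seg(rand_aa(10), "F"),
                               fill_consensus_seg(cons$AUTOIND),
                               seg(rand_aa(10), "F"),
                               fill_consensus_seg(cons$GERE)),
                          target_len %||% 450L),
    stop("unknown synthetic protein kind: ", kind, call. = FALSE)
  )
}

# per-member copy of a family base protein: consensus fixed positions
# mutated at `mutation_rate`, filler positions resampled at `variation`;
# protected positions never change, so planted truth is preserved
mutate_masked <- function(base, mutation_rate, variation) {
  chars <- strsplit(as.character(base), "")[[1]]
  mask <- attr(base, "mask")
  stopifnot(length(chars) == length(mask))
  mut <- function(idx, rate) {
    hit <- idx[stats::runif(length(idx)) < rate]
    if (length(hit)) chars[hit] <<- sample(FILLER_AA, length(hit),
                                           replace = TRUE)
  }
  if (mutation_rate > 0) mut(which(mask == "K"), mutation_rate)
  if (variation > 0) mut(which(mask == "F"), variation)
  paste(chars, collapse = "")
}

#' Family of related synthetic luxR genes
#'
#' Members share the same planted topology, motif class and cysteine plan
#' plus a family base sequence; downstream they should reunite as one clade
#' of the cladogram.
#'
#' @param name family id.
#' @param topology a topology label (counts for twin families are numbers
#'   of luxR genes and must be even; genes are planted in pairs).
#' @param count number of luxR genes.
#' @param motif_class `"AHL"`, `"NON_AHL"` or `"NEITHER"`.
#' @param motif_id placeholder motif id to plant (defaults by class).
#' @param autoind_cys,gere_cys,other_cys cysteine plan per member.
#' @param product gene product annotation text.
#' @return list describing the family.
#' @export
synthetic_family <- function(name, topology, count,
                             motif_class = c("AHL", "NON_AHL", "NEITHER"),
                             motif_id = NULL,
                             autoind_cys = 2L, gere_cys = 0L, other_cys = 1L,
                             product = "LuxR family transcriptional regulator") {
  motif_class <- match.arg(motif_class)
  if (is.null(motif_id)) {
    motif_id <- switch(motif_class, AHL = "ahl_p1", NON_AHL = "non_p1",
                       NEITHER = NA_character_)
  }
  if (topology %in% c("TWIN_RR_TANDEM", "TWIN_RR_DIVERGENT") &&
      count %% 2L != 0L) {
    stop("twin family counts must be even (genes come in pairs)",
         call. = FALSE)
  }
  list(name = name, topology = topology, count = as.integer(count),
       motif_class = motif_class, motif_id = motif_id,
       autoind_cys = as.integer(autoind_cys),
       gere_cys = as.integer(gere_cys), other_cys = as.integer(other_cys),
       product = product)
}

#' Default family panel of the synthetic census
#'
#' 60 luxR genes in 11 families: 15 circuit members across all circuit
#' classes, 14 twins, 31 plain solos — a 75% solo fraction, the headline
#' ratio of the survey this package models, at desk scale.  The RLI family
#' plants a constant 4 cysteines per member so the degenerate "4–4, 4"
#' statistics row arises from real clade data; one cysteine-rich solo family
#' mirrors the cysteine asymmetry observed between clades.
#'
#' @return list of [synthetic_family()] objects.
#' @export
default_luxr_families <- function() {
  list(
    synthetic_family("fam_ri_tandem", "RI_TANDEM", 4, "AHL", "ahl_p1",
                     autoind_cys = 2, other_cys = 0),
    synthetic_family("fam_ri_conv", "RI_CONVERGENT", 2, "AHL", "ahl_p2",
                     autoind_cys = 2, gere_cys = 1, other_cys = 0),
    synthetic_family("fam_ri_div", "RI_DIVERGENT", 2, "AHL", "ahl_p3",
                     autoind_cys = 3, other_cys = 0),
    synthetic_family("fam_rmi", "RMI", 3, "AHL", "ahl_p4",
                     autoind_cys = 4, other_cys = 1),
    synthetic_family("fam_rli", "RLI", 2, "AHL", "ahl_p5",
                     autoind_cys = 4, other_cys = 0),
    synthetic_family("fam_rxmi", "RXMI", 2, "AHL", "ahl_p6",
                     autoind_cys = 0, other_cys = 0),
    synthetic_family("fam_twin_tandem", "TWIN_RR_TANDEM", 8, "NON_AHL",
                     "non_p1", autoind_cys = 4, other_cys = 1),
    synthetic_family("fam_twin_div", "TWIN_RR_DIVERGENT", 6, "NON_AHL",
                     "non_p2", autoind_cys = 1, other_cys = 0),
    synthetic_family("fam_solo_ahl", "SOLO", 11, "AHL", "ahl_p7",
                     autoind_cys = 3, other_cys = 1),
    synthetic_family("fam_solo_nonahl", "SOLO", 12, "NON_AHL", "non_p3",
                     autoind_cys = 6, other_cys = 1),
    synthetic_family("fam_solo_neither", "SOLO", 8, "NEITHER",
                     autoind_cys = 1, other_cys = 0,
                     product = "hypothetical protein")
  )
}

#' Synthetic genome specification
#'
#' @param seed integer; a fixed seed implies bit-identical output.
#' @param families list of [synthetic_family()] objects.
#' @param decoy_counts named counts per decoy class (`GERE_ONLY`,
#'   `AUTOIND_ONLY`, `WRONG_ORDER`, `LENGTH_OUT`).
#' @param mutation_rate per-site substitution rate on consensus segments
#'   (0 = planted truth is recovered exactly).
#' @param member_variation per-site substitution rate on filler regions,
#'   giving within-family sequence variation without touching planted
#'   domains, motifs or cysteines.
#' @param include_edge_case also plant one solo luxR on a 2 kb contig, close
#'   enough to both contig ends that its assignment carries the edge flag.
#' @param genes_per_contig contig packing.
#' @param cassette_spacing_bp intergenic distance between successive
#'   cassettes, large enough that cassettes never interact under the default
#'   topology thresholds.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           families = default_luxr_families(),
                           decoy_counts = c(GERE_ONLY = 30L,
                                            AUTOIND_ONLY = 30L,
                                            WRONG_ORDER = 30L,
                                            LENGTH_OUT = 30L),
                           mutation_rate = 0,
                           member_variation = 0.02,
                           include_edge_case = TRUE,
                           genes_per_contig = 60L,
                           cassette_spacing_bp = 5000L) {
  stopifnot(all(decoy_counts >= 0), mutation_rate >= 0, mutation_rate <= 1,
            cassette_spacing_bp > 3400)
  structure(list(seed = as.integer(seed), families = families,
                 decoy_counts = decoy_counts,
                 mutation_rate = mutation_rate,
                 member_variation = member_variation,
                 include_edge_case = isTRUE(include_edge_case),
                 genes_per_contig = as.integer(genes_per_contig),
                 cassette_spacing_bp = as.integer(cassette_spacing_bp)),
            class = "synthetic_spec")
}

# cassette member plans: kind, strand, intergenic gap (bp) before this gene
cassette_plan <- function(topology) {
  switch(topology,
    RI_TANDEM = list(c("LUXR", "+", NA), c("LUXI", "+", 200)),
    RI_CONVERGENT = list(c("LUXR", "+", NA), c("LUXI", "-", 200)),
    RI_DIVERGENT = list(c("LUXR", "-", NA), c("LUXI", "+", 200)),
    RMI = list(c("LUXR", "+", NA), c("RSAM", "+", 200), c("LUXI", "+", 200)),
    RLI = list(c("LUXR", "+", NA), c("RSAL", "+", 200), c("LUXI", "+", 200)),
    RXMI = list(c("LUXR", "+", NA), c("XGENE", "+", 150),
                c("RSAM", "+", 150), c("LUXI", "+", 150)),
    TWIN_RR_TANDEM = list(c("LUXR", "+", NA), c("LUXR", "+", 150)),
    TWIN_RR_DIVERGENT = list(c("LUXR", "-", NA), c("LUXR", "+", 150)),
    SOLO = list(c("LUXR", "+", NA)),
    stop("no cassette plan for ", topology, call. = FALSE)
  )
}

PARTNER_PRODUCTS <- c(LUXI = "acyl-homoserine-lactone synthase",
                      RSAM = "rsaM family quorum-sensing repressor",
                      RSAL = "rsaL family quorum-sensing repressor",
                      XGENE = "hypothetical protein")

DECOY_PRODUCTS <- c(GERE_ONLY = "two-component response regulator",
                    AUTOIND_ONLY = "periplasmic binding protein",
                    WRONG_ORDER = "putative DNA-binding regulator",
                    LENGTH_OUT = "sensor hybrid regulator")

back_translate <- function(protein) {
  paste0(paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

#' Generate synthetic genomes with planted truth
#'
#' Deterministic under `spec$seed`.  Cassettes are laid out with generous
#' spacing and a 3.5 kb margin to contig ends, so planted topology labels
#' are exactly what the classifier should recover (the optional edge-case
#' contig is the deliberate exception).  Optionally writes GFF3, nucleotide
#' FASTA, protein FASTA and the truth TSV.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir if non-NULL, write `synthetic.gff3`, `synthetic.fna`,
#'   `synthetic.faa` and `synthetic_truth.tsv` there.
#' @return list: `genome` (a `qs_genome`), `truth` (data frame with one row
#'   per planted gene: id, coordinates, strand, role, family,
#'   topology_label, motif_class, per-domain cysteine counts), `files`
#'   (named paths, or NULL).
#' @export
generate_synthetic_genomes <- function(spec = synthetic_spec(),
                                       out_dir = NULL) {
  with_seed(spec$seed, {
    plans <- list()
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("g%04d", gid)
    }

    partner_base <- list()  # shared partner proteins per kind
    partner_protein <- function(kind) {
      if (is.null(partner_base[[kind]])) {
        partner_base[[kind]] <<- synthetic_protein(kind)
      }
      mutate_masked(partner_base[[kind]], spec$mutation_rate,
                    spec$member_variation)
    }

    for (fam in spec$families) {
      plan <- cassette_plan(fam$topology)
      n_cassettes <- if (fam$topology %in%
                           c("TWIN_RR_TANDEM", "TWIN_RR_DIVERGENT")) {
        fam$count %/% 2L
      } else fam$count
      base_luxr <- synthetic_protein(
        "LUXR", autoind_cys = fam$autoind_cys, gere_cys = fam$gere_cys,
        other_cys = fam$other_cys, motif_id = fam$motif_id)
      for (ci in seq_len(n_cassettes)) {
        members <- lapply(plan, function(m) {
          kind <- m[1]
          prot <- if (kind == "LUXR") {
            mutate_masked(base_luxr, spec$mutation_rate,
                          spec$member_variation)
          } else {
            partner_protein(kind)
          }
          list(gene_id = next_id(), kind = kind,
               role = if (kind %in% names(DECOY_PRODUCTS) ||
                            kind == "XGENE") "NONE" else kind,
               strand = m[2],
               gap = if (is.na(m[3])) NA_integer_ else as.integer(m[3]),
               protein = prot,
               product = if (kind == "LUXR") fam$product
                         else PARTNER_PRODUCTS[[kind]],
               family = if (kind == "LUXR") fam$name else NA_character_,
               topology = if (kind == "LUXR") fam$topology
                          else NA_character_,
               motif_class = if (kind == "LUXR") fam$motif_class
                             else NA_character_,
               cys_autoind = if (kind == "LUXR") fam$autoind_cys
                             else NA_integer_,
               cys_gere = if (kind == "LUXR") fam$gere_cys else NA_integer_,
               cys_other = if (kind == "LUXR") fam$other_cys
                           else NA_integer_)
        })
        plans[[length(plans) + 1L]] <- members
      }
    }

    for (cls in names(spec$decoy_counts)) {
      base_decoy <- synthetic_protein(cls)
      for (k in seq_len(spec$decoy_counts[[cls]])) {
        plans[[length(plans) + 1L]] <- list(list(
          gene_id = next_id(), kind = cls, role = "NONE", strand = "+",
          gap = NA_integer_,
          protein = mutate_masked(base_decoy, spec$mutation_rate,
                                  spec$member_variation),
          product = DECOY_PRODUCTS[[cls]], family = NA_character_,
          topology = NA_character_, motif_class = NA_character_,
          cys_autoind = NA_integer_, cys_gere = NA_integer_,
          cys_other = NA_integer_))
      }
    }

    # lay cassettes onto contigs with a margin that keeps the edge flag off
    margin <- 3500L
    contigs <- list()
    truth <- list()
    ctg_n <- 0L
    i <- 1L
    while (i <= length(plans)) {
      ctg_n <- ctg_n + 1L
      cid <- sprintf("ctg%02d", ctg_n)
      rows <- list()
      last_end <- 0L
      n_genes <- 0L
      while (i <= length(plans) && n_genes < spec$genes_per_contig) {
        for (m in plans[[i]]) {
          gap <- if (is.na(m$gap)) spec$cassette_spacing_bp else m$gap
          start <- if (last_end == 0L) margin + 1L else last_end + gap + 1L
          nt <- back_translate(m$protein)
          if (m$strand == "-") {
            nt <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(nt)))
          }
          end <- start + nchar(nt) - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = m$gene_id, contig_id = cid, start = start, end = end,
            strand = m$strand, product = m$product, protein = m$protein,
            nt = nt, kind = m$kind, role = m$role, family = m$family,
            topology_label = m$topology, motif_class = m$motif_class,
            cys_autoind = m$cys_autoind, cys_gere = m$cys_gere,
            cys_other = m$cys_other, stringsAsFactors = FALSE)
          last_end <- end
          n_genes <- n_genes + 1L
        }
        i <- i + 1L
      }
      rows <- do.call(rbind, rows)
      contigs[[cid]] <- list(rows = rows, length = last_end + margin)
      truth[[length(truth) + 1L]] <- rows
    }

    if (spec$include_edge_case) {
      prot <- mutate_masked(
        synthetic_protein("LUXR", autoind_cys = 1L, other_cys = 0L,
                          motif_id = "ahl_p8"),
        spec$mutation_rate, 0)
      nt <- back_translate(prot)
      rows <- data.frame(
        gene_id = next_id(), contig_id = "ctg_edge", start = 700L,
        end = 700L + nchar(nt) - 1L, strand = "+",
        product = "LuxR family transcriptional regulator", protein = prot,
        nt = nt, kind = "LUXR", role = "LUXR", family = "fam_edge",
        topology_label = "SOLO", motif_class = "AHL",
        cys_autoind = 1L, cys_gere = 0L, cys_other = 0L,
        stringsAsFactors = FALSE)
      contigs[["ctg_edge"]] <- list(rows = rows, length = rows$end + 638L)
      truth[[length(truth) + 1L]] <- rows
    }

    truth <- do.call(rbind, truth)

    qs_contigs <- lapply(names(contigs), function(cid) {
      rows <- contigs[[cid]]$rows
      qs_contig(cid, contigs[[cid]]$length,
                gene_table(rows$gene_id, cid, rows$start, rows$end,
                           rows$strand, rows$product, rows$protein))
    })
    genome <- qs_genome("synthetic", qs_contigs, "draft")

    truth_out <- truth[, c("gene_id", "contig_id", "start", "end", "strand",
                           "kind", "role", "family", "topology_label",
                           "motif_class", "cys_autoind", "cys_gere",
                           "cys_other")]
    truth_out$cys_total <- truth_out$cys_autoind + truth_out$cys_gere +
      truth_out$cys_other
    rownames(truth_out) <- NULL

    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- write_synthetic_files(contigs, truth_out, out_dir)
    }
    list(genome = genome, truth = truth_out, files = files)
  })
}

write_synthetic_files <- function(contigs, truth, out_dir) {
  gff <- file.path(out_dir, "synthetic.gff3")
  fna <- file.path(out_dir, "synthetic.fna")
  faa <- file.path(out_dir, "synthetic.faa")
  tsv <- file.path(out_dir, "synthetic_truth.tsv")

  lines <- "##gff-version 3"
  dna <- character()
  prot <- character()
  for (cid in names(contigs)) {
    rows <- contigs[[cid]]$rows
    clen <- contigs[[cid]]$length
    lines <- c(lines, paste("##sequence-region", cid, 1, clen))
    # contig sequence: seeded random filler with gene sequences spliced in
    seq <- sample(c("A", "C", "G", "T"), clen, replace = TRUE)
    for (k in seq_len(nrow(rows))) {
      seq[rows$start[k]:rows$end[k]] <- strsplit(rows$nt[k], "")[[1]]
    }
    dna[cid] <- paste(seq, collapse = "")
    lines <- c(lines, vapply(seq_len(nrow(rows)), function(k) {
      paste(cid, "luxrsolo_synthetic", "CDS", rows$start[k], rows$end[k],
            ".", rows$strand[k], "0",
            paste0("ID=", rows$gene_id[k], ";product=", rows$product[k]),
            sep = "\t")
    }, character(1)))
    prot[rows$gene_id] <- rows$protein
  }
  writeLines(lines, gff)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(dna), fna)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot), faa)
  write_tsv_table(truth, tsv)
  c(gff = gff, dna = fna, protein = faa, truth = tsv)
}
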