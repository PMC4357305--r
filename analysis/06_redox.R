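#!/usr/bin/env Rscript
# Step 6 — cysteine statistics per clade (min–max, average layout) and the
# disulfide screen: conserved cysteine columns of each clade mapped onto a
# C-alpha template, pairs within disulfide range reported per chain.
#
# The shipped run uses a synthetic helix template (the real analysis maps
# onto the TraR co-crystal, PDB 1H0M; point `tpl_path` at a local copy to
# reproduce it — the entry is not redistributed with this repository).
source("analysis/00_common.R")

genome <- load_genome()
det <- load_detections()
motifs <- read_tsv_table(file.path(res_dir, "motifs.tsv"))
clades_tbl <- read_tsv_table(file.path(res_dir, "clades.tsv"))
clades <- split(clades_tbl$gene_id, clades_tbl$clade_id)
genes <- genome_genes(genome)
luxr <- genes[genes$gene_id %in% det$gene_id[det$role == "LUXR"], ]

cys <- luxr_cys_table(luxr, det)
write_tsv_table(cys, file.path(res_dir, "cysteines.tsv"))
stats_tbl <- clade_stats_table(clades, motifs, cys)
write_tsv_table(stats_tbl, file.path(res_dir, "clade_stats.tsv"))
cat("per-clade cysteine content (min–max, average):\n")
print(stats_tbl[, c("clade_id", "n_members", "motif_consensus",
                    "cys_content")])

tpl_path <- system.file("extdata", "1h0m_ca.pdb", package = "luxrsolo")
tpl <- if (nzchar(tpl_path) && file.exists(tpl_path)) {
  cat("\nusing local 1H0M template\n")
  read_template(tpl_path, source_id = "1H0M")
} else {
  cat("\nno local 1H0M copy; using the synthetic helix template\n")
  synthetic_template(120, chains = c("A", "B"))
}
screen <- clade_disulfide_screen(clades, genes, det, tpl, cutoff = 6.8)
write_tsv_table(screen, file.path(res_dir, "disulfides.tsv"))
cat(sprintf("predicted pairs within 6.8 A: %d\n", nrow(screen)))
if (nrow(screen)) print(screen)
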