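#!/usr/bin/env Rscript
# Step 5 — LuxR similarity cladogram: pairwise global alignments (BLOSUM62,
# affine gaps) -> 1 - identity distances -> neighbor joining; clades are
# complete subtrees below a within-clade path-distance threshold.  Leaves
# are annotated id|topology|motif|cys for inspection.
source("analysis/00_common.R")

genome <- load_genome()
det <- load_detections()
asn <- read_tsv_table(file.path(res_dir, "topology.tsv"))
motifs <- read_tsv_table(file.path(res_dir, "motifs.tsv"))
genes <- genome_genes(genome)
luxr <- genes[genes$gene_id %in% det$gene_id[det$role == "LUXR"], ]

d <- identity_distance_matrix(setNames(luxr$protein_seq, luxr$gene_id))
write_phylip_distances(d, file.path(res_dir, "luxr_distances.phy"))
tree <- build_nj_tree(d)
clades <- extract_clades(tree, 0.3)
write_tsv_table(clades_as_table(clades), file.path(res_dir, "clades.tsv"))

cys <- luxr_cys_table(luxr, det)
ann <- annotate_tree_leaves(
  tree,
  topology = setNames(asn$label, asn$luxr_gene_id),
  motif = setNames(motifs$label, motifs$gene_id),
  cys = setNames(cys$total_cys, cys$gene_id))
ape::write.tree(ann, file.path(res_dir, "luxr_tree.nwk"))

cat(sprintf("%d LuxR sequences -> %d clades (threshold 0.3)\n",
            nrow(luxr), length(clades)))
print(lengths(clades))
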