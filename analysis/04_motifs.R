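#!/usr/bin/env Rscript
# Step 4 — AHL-binding / non-AHL-binding motif labels for every LuxR
# protein, from the (placeholder) PROSITE-style motif config.
source("analysis/00_common.R")

genome <- load_genome()
det <- load_detections()
genes <- genome_genes(genome)
luxr <- genes[genes$gene_id %in% det$gene_id[det$role == "LUXR"], ]
labs <- motif_labels(luxr, parse_motif_config())
write_tsv_table(labs, file.path(res_dir, "motifs.tsv"))
cat("motif label counts:\n")
print(table(labs$label))
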