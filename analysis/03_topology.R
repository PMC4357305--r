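#!/usr/bin/env Rscript
# Step 3 — chromosomal-neighborhood topology for every validated luxR:
# circuits (RI tandem/convergent/divergent, RMI, RLI, RXMI), twin-luxR
# arrangements, or solo; solos within 3 kb of a contig end carry the edge
# flag (draft-assembly honesty).
source("analysis/00_common.R")

genome <- load_genome()
det <- load_detections()
asn <- classify_topologies(genome, det, topology_config())
write_tsv_table(asn, file.path(res_dir, "topology.tsv"))

cs <- census_summary(asn, genome_genes(genome))
write_tsv_table(census_as_table(cs), file.path(res_dir, "census.tsv"))
print(cs)
cat("edge-flagged assignments:", sum(asn$edge_flag), "\n")
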