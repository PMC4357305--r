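#!/usr/bin/env Rscript
# Step 1 — build the study's synthetic genome set.
#
# The generator plants 60 luxR genes in 11 families covering every circuit,
# twin and solo topology class (45/60 = 75% solos, the headline solo share
# of the genome survey this package models), ~24 partner genes (luxI, rsaM,
# rsaL, X), 120 decoy genes (30 per failure mode of the dual-domain rule),
# and one deliberately edge-truncated solo on a 2 kb contig.
source("analysis/00_common.R")

seed <- 1L
gen <- generate_synthetic_genomes(synthetic_spec(seed = seed),
                                  out_dir = syn_dir)
cat(sprintf("planted %d genes (%d luxR) on %d contigs; seed %d\n",
            nrow(gen$truth), sum(gen$truth$role == "LUXR"),
            length(gen$genome$contigs), seed))
cat("wrote:", paste(basename(gen$files), collapse = ", "),
    "->", syn_dir, "\n")
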