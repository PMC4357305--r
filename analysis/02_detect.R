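#!/usr/bin/env Rscript
# Step 2 — dual-domain LuxR detection over every annotated gene.
#
# A gene is called LUXR only if it has both the autoinducer-binding and the
# GerE DNA-binding domain, in that order, within the LuxR length window;
# LUXI/RSAM/RSAL by their single domains.  Decoys must fail with named
# diagnostics.
source("analysis/00_common.R")

genome <- load_genome()
det <- qs_scan_genome(genome, detection_config())
write_tsv_table(det, file.path(res_dir, "detections.tsv"))

cat("role counts:\n")
print(table(det$role))
rejected <- det[det$role == "NONE" & nzchar(det$diagnostics), ]
cat("\ndiagnostics among rejected genes:\n")
print(sort(table(unlist(strsplit(rejected$diagnostics, ",")))))
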