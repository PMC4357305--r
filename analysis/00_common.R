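# Shared setup for the analysis drivers: paths and the lazily-loaded inputs
# produced by earlier steps.  Every step can be re-run on its own; each is a
# pure function of the files it reads.
library(luxrsolo)

res_dir <- "results"
syn_dir <- file.path(res_dir, "synthetic")
dir.create(syn_dir, recursive = TRUE, showWarnings = FALSE)

load_genome <- function() {
  read_annotated_genome(file.path(syn_dir, "synthetic"), "gff3+fasta",
                        genome_id = "synthetic", assembly_status = "draft")
}
load_truth <- function() read_tsv_table(file.path(syn_dir,
                                                  "synthetic_truth.tsv"))
load_detections <- function() read_tsv_table(file.path(res_dir,
                                                       "detections.tsv"))
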