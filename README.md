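# luxrsolo

An R package for taking a census of **solo (orphan) LuxR genes** in
annotated bacterial genomes.

In N-acyl homoserine lactone (AHL) quorum sensing, the LuxR-family receptor
is usually encoded next to the LuxI-family synthase that makes its signal.
Solo *luxR* genes have no *luxI* in their chromosomal vicinity and may sense
signals made elsewhere in the genome — or external, possibly non-AHL,
signals.  `luxrsolo` implements the full census workflow for people studying
these genes:

* **Detection** — a gene is called LuxR only if its protein carries both the
  autoinducer-binding domain (PF03472-type) and the GerE DNA-binding domain
  (PF00196-type), with the autoinducer domain N-terminal, and a length in
  the LuxR range (default 150–300 aa).  Both domains are individually
  promiscuous across bacterial proteomes; the architecture rule is what
  keeps false positives out.  Backends: an external HMMER driver for real
  profiles, and a built-in deterministic consensus matcher for offline
  testing.
* **Topology** — each validated luxR's neighborhood is classified, in
  precedence order, as a circuit (RI tandem/convergent/divergent, RMI, RLI,
  RXMI), a twin-luxR arrangement (tandem or divergent solo pairs), or solo:

  a luxR is **solo** iff no luxI lies within 3000 bp up- or downstream
  (3400 bp for the four-gene RXMI layout), with twin pairs counted among
  the solos.  Assignments within 3 kb of a contig end carry an `edge_flag`.
* **Motifs** — AHL-binding vs non-AHL-binding consensus motifs
  (PROSITE-style, editable config) label every LuxR as
  AHL / NON_AHL / BOTH / NEITHER.
* **Cladogram** — global affine-gap alignments (BLOSUM62, Gotoh DP in C++),
  distance = 1 − identity, deterministic neighbor joining, clade extraction,
  annotated Newick export (`id|topology|motif|cys`).
* **Redox screen** — per-domain cysteine counts, per-clade "min–max,
  average" cysteine statistics, and mapping of conserved cysteines onto a
  TraR-type Cα template (PDB 1H0M in the original analysis) to flag pairs
  within Cα–Cα disulfide range.
* **Synthetic study sets** — a deterministic generator plants cassettes of
  every topology class, motif instances, cysteine plans and four decoy
  classes, with a machine-readable truth table, so the whole pipeline is
  testable end to end without downloads.

## Worked example

```r
library(luxrsolo)

gen <- generate_synthetic_genomes(synthetic_spec(seed = 1))
cen <- run_census(gen$genome)
print(cen$census)
#> LuxR census
#>   total luxR:      61 (8 hypothetical)
#>   circuit members: 15
#>   solos:           46 (14 in twin arrangements)
#>   solo fraction:   75.4%
#>   per label:
#>     RI_TANDEM          4
#>     RI_CONVERGENT      2
#>     RI_DIVERGENT       2
#>     RMI                3
#>     RLI                2
#>     RXMI               2
#>     TWIN_RR_TANDEM     8
#>     TWIN_RR_DIVERGENT  6
#>     SOLO               32

truth_mismatches(cen, gen$truth)$total
#> [1] 0
```

61 luxR genes were planted (60 in eleven families plus one edge-case solo
on a 2 kb contig); 46 of them (75.4%) have no luxI within the distance rule
and are solos, 14 of those in twin arrangements — and every detected role,
topology label, motif label and cysteine count agrees with the generator's
truth table.  Per-gene assignments look like:

```r
head(cen$assignments[, c("luxr_gene_id", "label", "partner_ids",
                         "gap_bp", "is_solo")], 3)
#>   luxr_gene_id     label partner_ids gap_bp is_solo
#> 1        g0001 RI_TANDEM       g0002    200   FALSE
#> 2        g0003 RI_TANDEM       g0004    200   FALSE
#> 3        g0005 RI_TANDEM       g0006    200   FALSE
```

For real data: `read_annotated_genome()` ingests GFF3+FASTA or GenBank flat
files, and `detection_config(backend = "profile-hmm", profiles = ...)`
drives HMMER with your PF03472/PF00196/PF00765 profiles.  The shipped motif
config contains placeholder patterns — transcribe the published motif sets
into it before production use (see `?default_motif_config`).

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_report.R` are thin numbered drivers
over the package: simulate the study set, detect roles, classify topologies,
label motifs, build the cladogram, run the cysteine/disulfide screen, and
produce the aggregate census with a closed-loop audit against planted truth.
Each step reads and writes plain TSV under `results/`, so every intermediate
is inspectable:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## Limitations

The built-in consensus detection backend is a test instrument, not a
homology search — real scans need real profiles through the HMMER backend.
The cladogram is a similarity summary, not a model-based phylogeny.  A
cysteine pair within Cα range is geometry, not proof of a disulfide in vivo.
See the methods vignette (`vignettes/solo-luxr-census.Rmd`) for the full
account of parameters, tie-breaks and design decisions.
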