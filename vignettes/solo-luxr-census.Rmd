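---
title: "A census pipeline for solo LuxR quorum-sensing genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A census pipeline for solo LuxR quorum-sensing genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxrsolo)
```

## The problem

In N-acyl homoserine lactone (AHL) quorum sensing, a LuxR-family receptor is
usually encoded next to the LuxI-family synthase that produces its signal.
"Solo" (orphan) *luxR* genes break this pattern: they have no *luxI* in their
chromosomal vicinity and may respond to signals produced elsewhere in the
genome, or to external — possibly non-AHL — signals.  Counting solos reliably
is harder than it sounds, for two reasons this package takes seriously:

* **Detection is confounded by domain promiscuity.**  LuxR is a two-domain
  protein — an N-terminal autoinducer-binding domain (PFAM PF03472) and a
  C-terminal GerE-type helix-turn-helix DNA-binding domain (PF00196) — and
  both domains occur in hundreds of unrelated architectures.  A single-domain
  match is weak evidence.  The detector therefore requires *both* domains,
  *in the canonical N-to-C order*, within a plausible protein length range.
* **"Solo" is a statement about a neighborhood, not a gene.**  A *luxR* is
  solo only relative to a distance rule and a catalogue of known circuit
  layouts.  On draft assemblies, a partner gene can be missing from the
  contig rather than from the genome, so every assignment near a contig end
  carries an explicit edge flag instead of a silent guess.

## The pipeline

1. **Genome IO** (`read_annotated_genome`): GFF3+FASTA or GenBank flat files
   into a uniform gene-record model.  Coordinates are 1-based inclusive
   throughout; proteins come from the annotation when present, otherwise
   from translation table 11.  Genes with no recoverable protein are kept
   but flagged untranslatable and excluded from domain detection — the
   source data do not say how such ORFs should be treated, and exclusion is
   the conservative choice.
2. **Role detection** (`detect_domains`, `classify_gene`): the dual-domain
   rule for LUXR; a synthase domain plus a 120–250 aa window for LUXI;
   single-domain calls for the rsaM/rsaL accessory repressors, with a
   product-text fallback when no profile evidence is available.  Every
   rejection carries diagnostics (`MISSING_AUTOIND`, `MISSING_GERE`,
   `WRONG_ORDER`, `LENGTH_OUT_OF_RANGE`, `BELOW_THRESHOLD`).
3. **Topology** (`classify_neighborhood`): circuits first (RI in its three
   orientations, RMI, RLI, RXMI), then twin-luxR arrangements (tandem or
   divergent pairs of solos), then plain SOLO.
4. **Motifs** (`scan_motifs`): AHL-binding / non-AHL-binding consensus
   motifs in PROSITE-style syntax, from an editable config.
5. **Cladogram** (`pairwise_align`, `build_nj_tree`, `extract_clades`):
   global affine-gap alignments, 1 − identity distances, neighbor joining,
   threshold-based clade extraction.
6. **Redox screen** (`cys_profile`, `conserved_cys_columns`,
   `map_positions_to_template`, `predict_disulfides`): per-domain cysteine
   statistics and a structural screen that maps conserved cysteines of a
   clade onto a TraR-type Cα template and reports pairs within disulfide
   range.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| LuxR length window | 150–300 aa | canonical members (TraR, LuxR, QscR) are ~210–260 aa; the margin absorbs family spread.  The length rule is stated in the literature without numbers, so the window is configurable and surfaced in the config object. |
| LuxI length window | 120–250 aa | same reasoning for the synthase family. |
| simple circuit distance | 3000 bp | the canonical vicinity rule for RI/RMI/RLI circuits.  *Within* is read as inclusive: a gap of exactly 3000 bp is a circuit, 3001 bp is not.  The sources use both "within" and "less than"; the package resolves the one-bp ambiguity as ≤ and documents it here. |
| RXMI distance | 3400 bp | wider window for the four-gene RXMI layout. |
| twin search distance | 3000 bp | no separate figure exists for "adjacent" twin luxRs; the circuit vicinity is reused and is configurable. |
| E-value cutoff | 1e-5 per domain | HMM screening threshold (profile-hmm backend); the source survey names HMMER but prints no cutoff. |
| gap penalties | BLOSUM62, open 10, extend 0.5 | conventional protein alignment defaults; a gap of length L costs open + L·extend. |
| distance | 1 − fractional identity | the simplest defensible reading of "sequence similarity clustering"; pluggable. |
| clade threshold | 0.3 path distance | separates families differing over ~half their residues from families differing by a few percent; used only for reporting, all per-gene outputs are threshold-free. |
| Cα–Cα cutoff | 6.8 Å | upper end of Cα–Cα distances observed across disulfide surveys; genuine bridges typically sit near 4–6 Å, so the default is permissive and configurable. |

## Decision details and tie-breaks

* **Domain order** is compared via the `q_start` of the best-scoring hit of
  each kind, so overlapping or repeated hits cannot flip the order test.
* **Precedence** is circuit > twin > solo.  A luxI within range always
  defines a circuit; twin arrangements are a subtype of solo (`is_solo` is
  true for them).  Convergent adjacent luxR pairs are *not* a twin class —
  only tandem and divergent twin layouts exist in the catalogue — so such a
  pair is classified SOLO with a warning.
* **RXMI internal order**: the catalogue does not fix whether the extra gene
  X precedes or follows rsaM; both internal orders are accepted.
* **Gap distance** is the intergenic edge-to-edge gap
  (`max(0, later start − earlier end − 1)`), because "up and downstream" of
  a gene naturally measures from its boundaries; overlapping or abutting
  genes have gap 0.
* **Alignment traceback** prefers the diagonal move, then the gap that
  consumes the first sequence, then the other gap, so alignments (not just
  scores) are reproducible bit for bit.
* **Neighbor joining** breaks Q-matrix ties by the lexicographically
  smallest pair of cluster ids; negative branch-length estimates are clamped
  to zero with a log note.  The NJ "root" trifurcation is arbitrary, so
  clade extraction midpoint-roots the tree first — without this, a tight
  family that happens to contain the representation root shatters into
  singletons.
* **Center-star MSA** (for conserved-cysteine columns) anchors on the
  sequence with the highest summed identity, lexicographically first id on
  ties, and propagates gaps ("once a gap, always a gap").  It is adequate
  for the high-identity within-clade sets it is applied to and is not a
  general MSA replacement.
* **Degenerate inputs**: an annotation-free genome yields an all-zero
  census with an undefined (absent) solo fraction; a single-member clade
  reports its own cysteines; template positions missing from a chain are
  skipped with a warning, never fabricated.

## The synthetic study set

`generate_synthetic_genomes()` is first-class, tested code: it is how the
pipeline is validated offline, end to end.  The default specification
plants, deterministically under one seed:

* 60 luxR genes in 11 sequence families — 15 circuit members (4 RI tandem,
  2 RI convergent, 2 RI divergent, 3 RMI, 2 RLI, 2 RXMI), 14 twins (4
  tandem pairs, 3 divergent pairs) and 31 plain solos.  45/60 = 75% solos
  reproduces, at desk scale, the headline solo share of the genome survey
  this package models.  One extra solo sits on a deliberately short 2 kb
  contig to exercise the edge flag.
* the families' partner genes (luxI, rsaM, rsaL, X) at planted intergenic
  gaps that respect the distance thresholds;
* 30 decoys per failure mode of the dual-domain rule (GerE-only,
  autoinducer-only, wrong domain order, out-of-length-range);
* per-family motif classes and per-domain cysteine plans: the RLI family
  plants a constant 4 cysteines per member (so the degenerate
  "4–4, 4" statistics row arises from real clade data) and one solo family
  is cysteine-rich, mirroring the cysteine asymmetry between clades that
  motivates the redox hypothesis.

Two idealisations make planted truth exact by construction, and they bound
what passing tests prove.  Filler residues are drawn from an alphabet
without C and W: cysteine counts therefore come only from planted cysteines,
and motif matches only from planted instances (every placeholder motif is
W-anchored).  And the domain "profiles" of the consensus-pattern backend are
fixed arbitrary segments shared with the generator — **not** PFAM models.
Consequently the closed-loop results demonstrate the correctness of the
bookkeeping — coordinates, strand logic, thresholds, precedence, label
algebra, counting — not the sensitivity of real PF03472/PF00196 profiles on
real proteomes.  For real genomes, the `profile-hmm` backend delegates to
HMMER with user-supplied profiles, and detection quality is inherited from
those profiles.

The mutation-rate dial substitutes consensus positions at a chosen per-site
rate; detection recall over rates {0, 0.05, 0.1, 0.2} is checked to be
non-increasing, which exercises the mismatch-tolerance machinery without
claiming anything about real evolutionary divergence.

## Motif catalogue caveat

The 8 AHL-binding and 3 non-AHL-binding motifs used by the original survey
are cited there, not printed.  The shipped `motifs_default.tsv` therefore
contains clearly-marked placeholder patterns (which the generator plants);
transcribe the real motifs from the cited literature into a copy of the
config before drawing biological conclusions.  `BOTH` is kept as an explicit
label rather than an error so the either/or behaviour of the real motif sets
becomes a checkable property of a dataset rather than an assumption.

## Structural template

The disulfide screen is defined against any Cα template; the analysis it
models used the TraR–AHL–DNA co-crystal (PDB 1H0M), an *active* conformation
of a LuxR-family dimer — which is what makes a predicted bridge there
interpretable as reinforcing the active state.  PDB coordinate files are not
redistributed with this package: place a local copy at
`inst/extdata/1h0m_ca.pdb` (Cα records suffice) to run the screen against
the real template; unit tests use synthetic templates
(`synthetic_template()`, clearly labelled) with hand-computed geometry.
Distances are reported per chain (default chain A) to 1 decimal.  Note the
published numbering for this screen is internally inconsistent between the
bridge table (e.g. 116/78, 174/47) and the corresponding structure figure
(A82–A116, A48–A169); this package reports template numbering exactly as
parsed from the file and does not attempt to reconcile the two.

## Problem sizes

The shipped analysis and the test suite run the default synthetic set
(205 planted genes, 61 LuxR sequences, 1830 pairwise alignments for the
cladogram), 50 brute-force alignment oracles at length ≤ 8, and 100
neighbor-joining oracle replicates on ≤ 6 leaves — sizes chosen so the whole
loop stays interactive on a laptop while every code path is exercised.

## Known limitations

* The consensus-pattern backend is a test instrument, not a homology search;
  real scans need the profile-hmm backend and real profiles.
* Distances and neighbor joining are the simplest defensible choices; the
  cladogram is a similarity summary, not a phylogenetic estimate (no model
  of substitution, no support values).
* The catalogue covers the topology classes named above; rarer multi-X
  layouts from the wider topology literature are out of scope.
* Cross-contig partners are never considered; the edge flag is the honesty
  mechanism, not a rescue.
* A predicted Cα-range cysteine pair is a geometric statement only; it is
  no proof of disulfide formation in vivo.
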