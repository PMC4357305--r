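# Shipped configuration and fixtures

- `motifs_default.tsv` — PLACEHOLDER motif patterns for the AHL-binding /
  non-AHL-binding classifier.  The real 8 AHL and 3 non-AHL consensus motifs
  originate in the cited literature (Covaceuszach et al.; Gonzalez & Venturi;
  Patel et al.) and are not redistributed here: transcribe them into a copy of
  this file before production use.  The placeholders are the patterns the
  synthetic-genome generator plants, so the whole pipeline is testable offline.
- `1h0m_ca.pdb` — NOT shipped.  Place a local C-alpha (or full-atom) copy of
  PDB entry 1H0M here to enable the TraR-template disulfide screen against the
  real structure; all structural unit tests run on synthetic templates and do
  not require it.
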