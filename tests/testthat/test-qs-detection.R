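cons <- qs_consensus_segments()
fill <- function(x) gsub("x", "A", x)

test_that("a verbatim consensus segment is found at its planted span", {
  seq <- paste0(strrep("G", 9), fill(cons$AUTOIND), strrep("G", 20))
  hits <- detect_domains(seq, detection_config(max_mismatch = 0))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$domain_kind, "AUTOIND")
  expect_equal(hits$q_start, 10L)
  expect_equal(hits$q_end, 9L + nchar(cons$AUTOIND))
})

test_that("random sequences produce no false hits at zero mismatch tolerance", {
  set.seed(5)
  cfg <- detection_config(max_mismatch = 0)
  n_hits <- vapply(1:100, function(i) {
    nrow(detect_domains(random_protein(200), cfg))
  }, integer(1))
  expect_identical(sum(n_hits), 0L)
})

test_that("two planted domains are reported in ascending query order", {
  seq <- paste0(strrep("G", 9), fill(cons$AUTOIND), strrep("G", 10),
                fill(cons$GERE), strrep("G", 10))
  hits <- detect_domains(seq, detection_config())
  expect_equal(hits$domain_kind, c("AUTOIND", "GERE"))
  expect_true(hits$q_start[1] < hits$q_start[2])
})

test_that("the dual-domain rule accepts the canonical architecture and rejects each decoy class with the right diagnostics", {
  cfg <- detection_config()
  call_kind <- function(kind, ...) {
    set.seed(91)
    p <- as.character(synthetic_protein(kind, ...))
    g <- list(gene_id = "x", protein_seq = p, product = "")
    classify_gene(g, detect_domains(p, cfg), cfg)
  }
  ok <- call_kind("LUXR", autoind_cys = 2, other_cys = 1,
                  motif_id = "ahl_p1")
  expect_equal(ok$role, "LUXR")
  expect_length(ok$diagnostics, 0L)

  gere_only <- call_kind("GERE_ONLY")
  expect_equal(gere_only$role, "NONE")
  expect_equal(gere_only$diagnostics, "MISSING_AUTOIND")

  autoind_only <- call_kind("AUTOIND_ONLY")
  expect_equal(autoind_only$role, "NONE")
  expect_equal(autoind_only$diagnostics, "MISSING_GERE")

  wrong <- call_kind("WRONG_ORDER")
  expect_equal(wrong$role, "NONE")
  expect_equal(wrong$diagnostics, "WRONG_ORDER")

  long <- call_kind("LENGTH_OUT")
  expect_equal(long$role, "NONE")
  expect_equal(long$diagnostics, "LENGTH_OUT_OF_RANGE")
})

test_that("LuxI, rsaM and rsaL are called from their single-domain hits; rsaM/rsaL fall back to product text", {
  cfg <- detection_config()
  set.seed(17)
  for (kind in c("LUXI", "RSAM", "RSAL")) {
    p <- as.character(synthetic_protein(kind))
    det <- classify_gene(list(gene_id = "x", protein_seq = p, product = ""),
                         detect_domains(p, cfg), cfg)
    expect_equal(det$role, kind)
  }
  # no domain evidence at all: product-text fallback
  p <- random_protein(80)
  det <- classify_gene(list(gene_id = "x", protein_seq = p,
                            product = "RsaM-like repressor"),
                       detect_domains(p, cfg), cfg)
  expect_equal(det$role, "RSAM")
})

test_that("detection is deterministic and tolerates mismatches up to the configured k", {
  chars <- strsplit(fill(cons$AUTOIND), "")[[1]]
  fixed <- which(strsplit(cons$AUTOIND, "")[[1]] != "x")
  chars[fixed[c(3, 30)]] <- "G"  # 2 mismatches at fixed positions
  seq <- paste0("M", paste(chars, collapse = ""), strrep("G", 30))
  h2 <- detect_domains(seq, detection_config(max_mismatch = 2))
  h1 <- detect_domains(seq, detection_config(max_mismatch = 1))
  expect_equal(nrow(h2), 1L)
  expect_equal(nrow(h1), 0L)
  expect_identical(detect_domains(seq, detection_config()),
                   detect_domains(seq, detection_config()))
})

test_that("the profile-hmm backend drives the external HMMER engine and agrees on the planted domain", {
  dir <- withr::local_tempdir()
  set.seed(4)
  base <- gsub("x", "A", qs_consensus_segments()$AUTOIND)
  msa <- vapply(1:5, function(i) {
    ch <- strsplit(base, "")[[1]]
    ch[sample(length(ch), 2)] <- sample(c("G", "S", "T"), 2, TRUE)
    paste(ch, collapse = "")
  }, character(1))
  ali <- file.path(dir, "ali.fa")
  writeLines(c(rbind(paste0(">s", 1:5), msa)), ali)
  hmm <- file.path(dir, "autoind.hmm")
  status <- system2("hmmbuild", c("--amino", shQuote(hmm), shQuote(ali)),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  cfg <- detection_config(backend = "profile-hmm",
                          profiles = c(AUTOIND = hmm))
  prot <- as.character(synthetic_protein("AUTOIND_ONLY"))
  hits <- detect_domains(prot, cfg)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$domain_kind, "AUTOIND")
  # planted consensus sits right after the M + 10-residue pad
  expect_lt(abs(hits$q_start - 12L), 5L)
  expect_true(hits$evalue <= 1e-5)
})

test_that("untranslatable genes are excluded from detection but kept in the scan output", {
  genes <- gene_table(c("a", "b"), "c1", c(100, 1000), c(400, 1400),
                      c("+", "+"), "",
                      c(NA, as.character(synthetic_protein("XGENE"))))
  genome <- qs_genome("g", list(qs_contig("c1", 5000, genes)))
  det <- qs_scan_genome(genome)
  expect_equal(nrow(det), 2L)
  expect_equal(det$role[det$gene_id == "a"], "NONE")
  expect_match(det$diagnostics[det$gene_id == "a"], "UNTRANSLATABLE")
})
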