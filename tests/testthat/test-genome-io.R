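test_that("gene table TSV round-trips field-by-field", {
  set.seed(11)
  n <- 50
  starts <- sort(sample(1:100000, n))
  prods <- sample(c("LuxR family transcriptional regulator",
                    "hypothetical protein", "AHL synthase", ""), n, TRUE)
  prot <- ifelse(stats::runif(n) < 0.8,
                 vapply(seq_len(n), function(i) random_protein(30), ""),
                 NA_character_)
  genes <- gene_table(sprintf("g%03d", 1:n), "c1", starts,
                      starts + sample(300:900, n, TRUE),
                      sample(c("+", "-"), n, TRUE), prods, prot)
  path <- tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  back <- read_gene_table(path)
  expect_identical(back, genes)
  expect_identical(genes$is_hypothetical,
                   grepl("hypothetical", genes$product, ignore.case = TRUE))
})

test_that("empty gene table writes a header-only file", {
  path <- tempfile(fileext = ".tsv")
  write_gene_table(gene_table(character(), character(), integer(),
                              integer(), character()), path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_gene_table(path)), 0L)
})

test_that("GFF3 with zero CDS features yields one empty contig", {
  dir <- withr::local_tempdir()
  fx <- write_gff3_fixture(dir)
  g <- read_annotated_genome(fx, "gff3+fasta")
  expect_length(g$contigs, 1L)
  expect_equal(nrow(g$contigs[[1]]$genes), 0L)
  expect_equal(g$contigs[[1]]$length, 5000L)
})

test_that("generator output read back matches the truth table, via both the annotated-protein and translation routes", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(seed = 21,
                         families = list(
                           synthetic_family("f1", "RI_TANDEM", 2, "AHL"),
                           synthetic_family("f2", "SOLO", 2, "NON_AHL")),
                         decoy_counts = c(GERE_ONLY = 2L),
                         include_edge_case = FALSE)
  gen <- generate_synthetic_genomes(spec, out_dir = dir)
  g <- read_annotated_genome(file.path(dir, "synthetic"), "gff3+fasta")
  gt <- genome_genes(g)
  tr <- gen$truth
  idx <- match(tr$gene_id, gt$gene_id)
  expect_false(anyNA(idx))
  expect_equal(gt$start[idx], tr$start)
  expect_equal(gt$end[idx], tr$end)
  expect_equal(gt$strand[idx], tr$strand)
  prot_annot <- gt$protein_seq[idx]
  # drop the protein FASTA: proteins must be recovered by translation
  # (table 11) from the nucleotide sequence, identically
  file.remove(file.path(dir, "synthetic.faa"))
  g2 <- read_annotated_genome(file.path(dir, "synthetic"), "gff3+fasta")
  gt2 <- genome_genes(g2)
  expect_equal(gt2$protein_seq[match(tr$gene_id, gt2$gene_id)], prot_annot)
})

test_that("GenBank route yields the same coordinates as GFF3 and derives the hypothetical flag", {
  dir <- withr::local_tempdir()
  prot <- "MKLVDE"
  nt <- "ATGAAACTGGTTGATGAATAA"  # back-translation of MKLVDE + stop
  clen <- 300L
  dna <- paste0(strrep("A", 99), nt, strrep("G", clen - 99 - nchar(nt)))
  cds <- data.frame(id = "gA", start = 100L, end = 120L, strand = "+",
                    product = "hypothetical protein")
  fx <- write_gff3_fixture(dir, contig = "ctgZ", clen = clen, cds = cds,
                           dna = dna)
  g_gff <- read_annotated_genome(fx, "gff3+fasta")

  gb <- file.path(dir, "fix.gb")
  writeLines(c(
    sprintf("LOCUS       ctgZ         %d bp    DNA     linear   BCT 01-JAN-2020",
            clen),
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "     CDS             100..120",
    "                     /locus_tag=\"gA\"",
    "                     /product=\"hypothetical protein\"",
    sprintf("                     /translation=\"%s\"", prot),
    "ORIGIN",
    "//"), gb)
  g_gb <- read_annotated_genome(gb, "genbank")

  a <- genome_genes(g_gff)
  b <- genome_genes(g_gb)
  expect_equal(a[, c("start", "end", "strand")], b[, c("start", "end",
                                                       "strand")])
  expect_true(all(b$is_hypothetical))
  expect_equal(b$protein_seq, prot)
  expect_equal(a$protein_seq, prot)  # translated from nucleotide
})

test_that("minus-strand and compound GenBank locations are handled; out-of-bounds CDS are rejected with a warning", {
  dir <- withr::local_tempdir()
  gb <- file.path(dir, "multi.gb")
  writeLines(c(
    "LOCUS       ctgY         500 bp    DNA     linear   BCT 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(10..90)",
    "                     /locus_tag=\"neg\"",
    "                     /translation=\"MAAA\"",
    "     CDS             join(100..150,200..260)",
    "                     /locus_tag=\"jn\"",
    "                     /translation=\"MAAA\"",
    "     CDS             400..900",
    "                     /locus_tag=\"oob\"",
    "                     /translation=\"MAAA\"",
    "//"), gb)
  expect_warning(expect_warning(g <- read_annotated_genome(gb, "genbank"),
                                "joined"),
                 "out-of-bounds")
  genes <- genome_genes(g)
  expect_setequal(genes$gene_id, c("neg", "jn"))
  expect_equal(genes$strand[genes$gene_id == "neg"], "-")
  expect_true(genes$start[genes$gene_id == "neg"] <
                genes$end[genes$gene_id == "neg"])
  expect_equal(genes$start[genes$gene_id == "jn"], 100L)
  expect_equal(genes$end[genes$gene_id == "jn"], 260L)
})
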