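test_that("gene_gap measures intergenic edge-to-edge distance, clamps overlap, and is symmetric", {
  g <- gene_table(c("a", "b"), "c1", c(100, 701), c(500, 900), c("+", "+"))
  expect_equal(gene_gap(g[1, ], g[2, ]), 200L)
  ov <- gene_table(c("a", "b"), "c1", c(100, 400), c(500, 900), c("+", "+"))
  expect_equal(gene_gap(ov[1, ], ov[2, ]), 0L)
  # abutting genes
  ab <- gene_table(c("a", "b"), "c1", c(100, 501), c(500, 900), c("+", "+"))
  expect_equal(gene_gap(ab[1, ], ab[2, ]), 0L)
  set.seed(13)
  for (k in 1:200) {
    s <- sort(sample(1:50000, 4))
    p <- gene_table(c("a", "b"), "c1", s[c(1, 3)], s[c(2, 4)], c("+", "-"))
    expect_identical(gene_gap(p[1, ], p[2, ]), gene_gap(p[2, ], p[1, ]))
  }
  other <- gene_table("z", "c2", 10, 50, "+")
  expect_error(gene_gap(g[1, ], other[1, ]), "different contigs")
})

test_that("relative orientation distinguishes tandem, convergent and divergent pairs", {
  mk <- function(s1, s2) gene_table(c("r", "p"), "c1", c(100, 1000),
                                    c(800, 1600), c(s1, s2))
  g <- mk("+", "+")
  expect_equal(relative_orientation(g[1, ], g[2, ]), "TANDEM")
  g <- mk("+", "-")
  expect_equal(relative_orientation(g[1, ], g[2, ]), "CONVERGENT")
  g <- mk("-", "+")
  expect_equal(relative_orientation(g[1, ], g[2, ]), "DIVERGENT")
  # orientation is a property of the pair, not the argument order
  expect_equal(relative_orientation(g[2, ], g[1, ]), "DIVERGENT")
})

test_that("neighborhoods classify into circuits, twins and solos by the precedence rules", {
  # RI tandem, gap 200, nothing between
  gm <- mk_genome(c(4000, 4863), c(4662, 5320), c("+", "+"),
                  c("LUXR", "LUXI"))
  a <- classify_one(gm, "t1")
  expect_equal(a$label, "RI_TANDEM")
  expect_false(a$is_solo)
  expect_equal(a$gap_bp, 200L)
  expect_equal(a$partner_ids, "t2")

  # luxR-rsaM-luxI with a luxR<->luxI gap of 2500
  gm <- mk_genome(c(4000, 5001, 5501, 7163), c(4662, 5300, 5800, 7800),
                  c("+", "+", "+", "+"), c("LUXR", "RSAM", "LUXI", "NONE"))
  expect_equal(classify_one(gm, "t1")$label, "RMI")
  # rsaL instead
  gm$detections$role[2] <- "RSAL"
  expect_equal(classify_one(gm, "t1")$label, "RLI")

  # RXMI: rsaM plus one other gene between, in either internal order
  gm <- mk_genome(c(4000, 4863, 5500, 6200), c(4662, 5200, 5900, 6900),
                  c("+", "+", "+", "+"), c("LUXR", "NONE", "RSAM", "LUXI"))
  expect_equal(classify_one(gm, "t1")$label, "RXMI")
  gm$detections$role[2:3] <- c("RSAM", "NONE")
  expect_equal(classify_one(gm, "t1")$label, "RXMI")

  # two luxR genes, divergent, gap 150, no luxI
  gm <- mk_genome(c(4000, 4813), c(4662, 5400), c("-", "+"),
                  c("LUXR", "LUXR"))
  a1 <- classify_one(gm, "t1")
  a2 <- classify_one(gm, "t2")
  expect_equal(a1$label, "TWIN_RR_DIVERGENT")
  expect_equal(a2$label, "TWIN_RR_DIVERGENT")
  expect_true(a1$is_solo && a2$is_solo)
  # tandem twins
  gm <- mk_genome(c(4000, 4813), c(4662, 5400), c("+", "+"),
                  c("LUXR", "LUXR"))
  expect_equal(classify_one(gm, "t1")$label, "TWIN_RR_TANDEM")
  # convergent adjacent pair is not a twin class
  gm <- mk_genome(c(4000, 4813), c(4662, 5400), c("+", "-"),
                  c("LUXR", "LUXR"))
  expect_warning(a <- classify_one(gm, "t1"), "convergent")
  expect_equal(a$label, "SOLO")

  # lone luxR on a 2 kb contig: solo with the edge flag raised
  genes <- gene_table("t1", "small", 700, 1362, "+")
  genome <- qs_genome("g", list(qs_contig("small", 2000, genes)), "draft")
  det <- data.frame(gene_id = "t1", role = "LUXR")
  a <- classify_neighborhood(genome, genes[1, ], det)
  expect_equal(a$label, "SOLO")
  expect_true(a$edge_flag)
  expect_equal(a$partner_ids, "")
})

test_that("the distance thresholds are inclusive at the bound and exclusive one bp beyond", {
  ri_at_gap <- function(gap) {
    gm <- mk_genome(c(4000, 4663 + gap), c(4662, 5200 + gap), c("+", "+"),
                    c("LUXR", "LUXI"))
    classify_one(gm, "t1")
  }
  expect_equal(ri_at_gap(3000)$label, "RI_TANDEM")
  a <- ri_at_gap(3001)
  expect_equal(a$label, "SOLO")
  expect_true(a$is_solo)

  rxmi_at_span <- function(span) {
    # luxR | g1 | X(701bp) | g2 | rsaM(701bp) | g3 | luxI, total span fixed
    rest <- span - 1402
    g1 <- 500L
    g2 <- 500L
    g3 <- rest - g1 - g2
    x_start <- 4662 + g1 + 1
    m_start <- x_start + 701 + g2
    i_start <- m_start + 701 + g3
    gm <- mk_genome(c(4000, x_start, m_start, i_start),
                    c(4662, x_start + 700, m_start + 700, i_start + 700),
                    c("+", "+", "+", "+"),
                    c("LUXR", "NONE", "RSAM", "LUXI"))
    classify_one(gm, "t1")
  }
  expect_equal(rxmi_at_span(3400)$label, "RXMI")
  expect_equal(rxmi_at_span(3401)$label, "SOLO")
})

test_that("shrinking the simple distance never converts a solo into a circuit", {
  set.seed(29)
  for (k in 1:30) {
    gap <- sample(100:4000, 1)
    gm <- mk_genome(c(4000, 4663 + gap), c(4662, 5200 + gap), c("+", "+"),
                    c("LUXR", "LUXI"))
    wide <- classify_one(gm, "t1", topology_config())
    narrow <- classify_one(gm, "t1",
                           topology_config(simple_distance_bp = 1500,
                                           rxmi_distance_bp = 1700))
    if (wide$is_solo) expect_true(narrow$is_solo)
  }
})

test_that("the census partitions assignments and reports the solo fraction", {
  asn <- data.frame(
    luxr_gene_id = paste0("g", 1:4),
    label = c("SOLO", "SOLO", "TWIN_RR_TANDEM", "RI_TANDEM"),
    is_solo = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  cs <- census_summary(asn)
  expect_equal(cs$total_luxr, 4L)
  expect_equal(cs$solo_count, 3L)
  expect_equal(cs$circuit_count, 1L)
  expect_equal(cs$twin_count, 1L)
  expect_equal(cs$solo_fraction_percent, 75)
  expect_equal(sum(cs$per_label), cs$total_luxr)
  expect_equal(cs$circuit_count + cs$solo_count, cs$total_luxr)
  expect_lte(cs$twin_count, cs$solo_count)

  empty <- census_summary(asn[0, ])
  expect_equal(empty$total_luxr, 0L)
  expect_true(is.na(empty$solo_fraction_percent))
})
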