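mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(domain_kind = r[[1]], q_start = r[[2]], q_end = r[[3]],
               score = 1, evalue = 0, stringsAsFactors = FALSE)
  }))
}

test_that("cysteine profiles split counts by domain span and match a naive counter", {
  expect_equal(cys_profile("MKDLFTG")$total_cys, 0L)
  seq <- paste0("MAAA", "CACCA", strrep("A", 10), "C", strrep("A", 5))
  #        1-4   5-9 autoind span     20 other
  hits <- mk_hits(list("AUTOIND", 5L, 9L))
  p <- cys_profile(seq, hits)
  expect_equal(p$autoind_cys, 3L)
  expect_equal(p$other_cys, 1L)
  expect_equal(p$total_cys, 4L)
  expect_equal(p$gere_cys, 0L)

  set.seed(73)
  for (k in 1:100) {
    s <- random_protein(sample(20:100, 1),
                        letters = rownames(align_scoring()$matrix)[1:20])
    naive <- sum(strsplit(s, "")[[1]] == "C")
    expect_identical(cys_profile(s)$total_cys, naive)
  }
})

test_that("clade cysteine statistics use the min–max, average layout", {
  expect_equal(clade_cys_stats(c(4, 4, 4))$formatted, "4–4, 4")
  st <- clade_cys_stats(c(2, 3))
  expect_equal(st$formatted, "2–3, 2.5")
  st <- clade_cys_stats(c(7, 14))
  expect_equal(st$min_cys, 7)
  expect_equal(st$max_cys, 14)
  expect_true(st$min_cys <= st$mean_cys && st$mean_cys <= st$max_cys)
  expect_equal(clade_cys_stats(c(2, 2, 2, 3))$formatted, "2–3, 2.25")
  expect_error(clade_cys_stats(integer()), "empty")
})

test_that("the PDB reader keeps one C-alpha per residue, first altloc wins, and agrees with an independent parser", {
  dir <- withr::local_tempdir()
  p2 <- file.path(dir, "two.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  CYS A   2       4.000   6.000   3.000  1.00  0.00           C",
    "END"), p2)
  t <- read_template(p2)
  expect_equal(nrow(t$atoms), 2L)
  expect_equal(t$atoms$resid, c("A", "C"))
  expect_equal(t$atoms$x, c(1, 4))

  alt <- file.path(dir, "alt.pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "END"), alt)
  expect_warning(ta <- read_template(alt), "first occurrence")
  expect_equal(nrow(ta$atoms), 1L)
  expect_equal(ta$atoms$x, 1)

  none <- file.path(dir, "none.pdb")
  writeLines("END", none)
  expect_error(read_template(none))

  # cross-parser oracle on a larger synthetic template
  tpl <- synthetic_template(40, chains = c("A", "B"))
  path <- write_ca_pdb(tpl, file.path(dir, "syn.pdb"))
  mine <- read_template(path)
  ref <- naive_ca_parse(path)
  expect_equal(nrow(mine$atoms), nrow(ref))
  expect_equal(sum(mine$atoms$chain == "A"), sum(ref$chain == "A"))
  expect_equal(mine$atoms$x, ref$x, tolerance = 1e-6)
  expect_equal(mine$atoms$resno, ref$resno)
})

test_that("query positions map onto template numbering monotonically, shifting across deletions", {
  varied <- strrep("ACDEFGHIKLMNPQRSTVWY", 2)
  tpl <- synthetic_template(40, seq = varied)
  ts <- template_chain_seq(tpl)
  m <- map_positions_to_template(ts$seq, tpl)
  expect_identical(m, ts$resno)  # identity mapping

  # one internal deletion of 5 residues: downstream positions shift by 5
  del <- paste0(substr(ts$seq, 1, 10), substr(ts$seq, 16, 40))
  m2 <- map_positions_to_template(del, tpl)
  expect_identical(m2[1:10], 1:10)
  expect_identical(m2[11:35], 16:40)

  set.seed(79)
  for (k in 1:10) {
    ch <- strsplit(ts$seq, "")[[1]]
    i <- sample(40, 5)
    ch[i] <- sample(c("G", "S", "T", "E"), 5, TRUE)
    mm <- map_positions_to_template(paste(ch, collapse = ""), tpl)
    mapped <- mm[!is.na(mm)]
    expect_true(all(diff(mapped) > 0))
  }
})

test_that("the disulfide screen reports exactly the pairs within the cutoff, with hand-checked geometry", {
  # three collinear C-alphas at 3 A spacing, cutoff 4: only adjacent pairs
  atoms <- data.frame(chain = "A", resno = 1:3, resid = "C",
                      x = c(0, 3, 6), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  tpl <- structure(list(atoms = atoms, source_id = "synthetic"),
                   class = "template_structure")
  pairs <- predict_disulfides(1:3, tpl, cutoff = 4)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$ca_distance, c(3, 3))
  expect_setequal(paste(pairs$template_pos_1, pairs$template_pos_2),
                  c("1 2", "2 3"))

  expect_equal(nrow(predict_disulfides(1, tpl, cutoff = 4)), 0L)
  expect_warning(p <- predict_disulfides(c(1, 9), tpl, cutoff = 4),
                 "absent")
  expect_equal(nrow(p), 0L)
})

test_that("reported distances are invariant to rigid rotation and translation", {
  tpl <- synthetic_template(30)
  co <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  moved <- sweep(co %*% t(R), 2, c(10, -4, 2.5), `+`)
  tpl2 <- tpl
  tpl2$atoms[, c("x", "y", "z")] <- moved
  pos <- tpl$atoms$resno[tpl$atoms$resid == "C"]
  a <- predict_disulfides(pos, tpl, cutoff = 50)
  b <- predict_disulfides(pos, tpl2, cutoff = 50)
  expect_equal(a$ca_distance, b$ca_distance)
  # symmetry and triangle inequality over the reported pair set
  expect_true(all(a$ca_distance >= 0))
  d12 <- a$ca_distance[a$template_pos_1 == pos[1] &
                         a$template_pos_2 == pos[2]]
  expect_length(d12, 1L)
})

test_that("conserved cysteine columns require cysteine in every member", {
  msa <- c(s1 = "ACDEFC", s2 = "ACDEFC")
  expect_equal(conserved_cys_columns(msa), c(2L, 6L))
  msa <- c(s1 = "ACDEFC", s2 = "AADEFA")
  expect_length(conserved_cys_columns(msa), 0L)
  expect_error(conserved_cys_columns(c(s1 = "AC", s2 = "ACD")), "ragged")

  # planting k conserved columns in a synthetic clade yields exactly k
  set.seed(83)
  for (k in c(1, 3, 5)) {
    base <- strsplit(random_protein(50, strsplit("ADEFGHIKLMNPQRSTVY",
                                                 "")[[1]]), "")[[1]]
    cpos <- sample(50, k)
    base[cpos] <- "C"
    fam <- vapply(1:4, function(i) {
      ch <- base
      filler <- setdiff(seq_len(50), cpos)
      j <- sample(filler, 2)
      ch[j] <- sample(c("G", "S", "T"), 2, TRUE)
      paste(ch, collapse = "")
    }, character(1))
    names(fam) <- paste0("m", 1:4)
    msa <- center_star_msa(fam)
    expect_equal(length(conserved_cys_columns(msa)), k)
  }
})

test_that("the per-clade screen flags pairs inside versus outside the autoinducer domain span", {
  # template whose sequence carries adjacent cysteines at 5,6 (close in
  # space) and far-apart cysteines at 20 and 35
  seqchars <- rep("A", 40)
  seqchars[c(5, 6, 20, 35)] <- "C"
  tpl <- synthetic_template(40, seq = paste(seqchars, collapse = ""))
  ts <- template_chain_seq(tpl)
  genes <- gene_table(c("q1", "q2"), "c1", c(100, 1000), c(300, 1200),
                      c("+", "+"), "", c(ts$seq, ts$seq))
  detections <- data.frame(gene_id = c("q1", "q2"), role = "LUXR",
                           au_start = 1L, au_end = 10L,
                           gere_start = NA_integer_,
                           gere_end = NA_integer_,
                           stringsAsFactors = FALSE)
  clades <- list(clade1 = c("q1", "q2"))
  rep_tbl <- clade_disulfide_screen(clades, genes, detections, tpl,
                                    cutoff = 6.8)
  expect_gte(nrow(rep_tbl), 1L)
  close_pair <- rep_tbl[rep_tbl$template_pos_1 %in% c(5, 6) &
                          rep_tbl$template_pos_2 %in% c(5, 6), ]
  expect_equal(nrow(close_pair), 1L)
  expect_true(close_pair$in_autoind_domain)
  outside <- rep_tbl[rep_tbl$template_pos_1 > 10 |
                       rep_tbl$template_pos_2 > 10, ]
  if (nrow(outside)) expect_false(any(outside$in_autoind_domain))
})
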