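# Shared fixtures and independent oracles for the test suite.

# Brute-force global alignment score by exhaustive enumeration of all
# alignments (affine gaps: a gap of length L costs open + L * ext).  The
# oracle is recursion over explicit move sequences, independent of the DP
# implementation; only usable for short sequences.
bf_align_score <- function(a, b, scoring = align_scoring()) {
  sub <- scoring$matrix
  open <- scoring$gap_open
  ext <- scoring$gap_extend
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, sub[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(A)) {
      cost <- ext + if (prev != "U") open else 0
      best <- max(best, rec(i + 1L, j, "U") - cost)
    }
    if (j <= length(B)) {
      cost <- ext + if (prev != "L") open else 0
      best <- max(best, rec(i, j + 1L, "L") - cost)
    }
    best
  }
  rec(1L, 1L, "none")
}

random_protein <- function(n, letters = rownames(align_scoring()$matrix)[1:20]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# minimal genome builder for topology tests: coordinates + roles, no
# sequences needed
mk_genome <- function(starts, ends, strands, roles, contig_len = NULL,
                      contig_id = "c1", ids = NULL) {
  n <- length(starts)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (is.null(contig_len)) contig_len <- max(ends) + 5000L
  genes <- gene_table(ids, contig_id, starts, ends, strands)
  genome <- qs_genome("test", list(qs_contig(contig_id, contig_len, genes)))
  detections <- data.frame(gene_id = ids, role = roles,
                           stringsAsFactors = FALSE)
  list(genome = genome, detections = detections, genes = genes)
}

classify_one <- function(gm, id, config = topology_config()) {
  genes <- genome_genes(gm$genome)
  classify_neighborhood(gm$genome, genes[genes$gene_id == id, ][1, ],
                        gm$detections, config)
}

# PDB ATOM line writer for template fixtures
write_ca_pdb <- function(template, path) {
  at <- template$atoms
  three <- c(A = "ALA", C = "CYS", G = "GLY", S = "SER", L = "LEU",
             K = "LYS", E = "GLU", D = "ASP", F = "PHE", R = "ARG",
             T = "THR", V = "VAL", Y = "TYR", X = "UNK")
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, three[[at$resid[i]]] %||% "UNK", at$chain[i], at$resno[i],
            at$x[i], at$y[i], at$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent fixed-column PDB C-alpha parser (oracle for read_template)
naive_ca_parse <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") &
                   trimws(substr(lines, 13, 16)) == "CA"]
  data.frame(chain = trimws(substr(lines, 22, 22)),
             resno = as.integer(substr(lines, 23, 26)),
             x = as.numeric(substr(lines, 31, 38)),
             y = as.numeric(substr(lines, 39, 46)),
             z = as.numeric(substr(lines, 47, 54)),
             stringsAsFactors = FALSE)
}

# random additive tree on n leaves with strictly positive branch lengths;
# returns the tree and its leaf-to-leaf distance matrix
random_additive_tree <- function(n) {
  t <- ape::rtree(n, br = function(k) stats::runif(k, 0.2, 1))
  t$tip.label <- paste0("L", seq_len(n))
  list(tree = t, d = stats::cophenetic(t))
}

# small GFF3 + FASTA fixture writer
write_gff3_fixture <- function(dir, contig = "chrA", clen = 5000,
                               cds = NULL, dna = NULL) {
  gff <- file.path(dir, "fix.gff3")
  fna <- file.path(dir, "fix.fna")
  lines <- c("##gff-version 3",
             paste("##sequence-region", contig, 1, clen))
  if (!is.null(cds)) {
    lines <- c(lines, vapply(seq_len(nrow(cds)), function(i) {
      paste(contig, "test", "CDS", cds$start[i], cds$end[i], ".",
            cds$strand[i], "0",
            paste0("ID=", cds$id[i], ";product=", cds$product[i]),
            sep = "\t")
    }, character(1)))
  }
  writeLines(lines, gff)
  if (is.null(dna)) {
    dna <- paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
                 collapse = "")
  }
  writeLines(c(paste0(">", contig), dna), fna)
  c(gff = gff, dna = fna)
}
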