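# Uniform gene-record model.  Coordinates are 1-based inclusive (GenBank
# convention; GFF3 needs no shift).  Minus-strand genes keep start < end;
# orientation is carried only by the strand field.

GENE_TABLE_COLS <- c("gene_id", "contig_id", "start", "end", "strand",
                     "product", "protein_seq", "is_hypothetical")

#' Build a gene table
#'
#' @param gene_id,contig_id,start,end,strand,product,protein_seq vectors of
#'   equal length; `protein_seq` may be `NA` (gene kept but flagged
#'   untranslatable and excluded from domain detection).
#' @return data frame with the fixed gene-table columns;
#'   `is_hypothetical` is derived from the product text ("hypothetical",
#'   case-insensitive).
#' @export
gene_table <- function(gene_id, contig_id, start, end, strand,
                       product = "", protein_seq = NA_character_) {
  n <- length(gene_id)
  start <- as.integer(start)
  end <- as.integer(end)
  product <- rep_len(as.character(product), n)
  protein_seq <- rep_len(as.character(protein_seq), n)
  stopifnot(all(start >= 1L), all(end >= start), all(strand %in% c("+", "-")))
  ok <- !is.na(protein_seq)
  if (any(ok)) {
    for (p in protein_seq[ok]) assert_protein(p)
  }
  df <- data.frame(gene_id = as.character(gene_id),
                   contig_id = as.character(contig_id),
                   start = start, end = end,
                   strand = as.character(strand),
                   product = as.character(product),
                   protein_seq = as.character(protein_seq),
                   is_hypothetical = grepl("hypothetical", product,
                                           ignore.case = TRUE),
                   stringsAsFactors = FALSE)
  sort_genes(df)
}

sort_genes <- function(df) {
  df <- df[order(df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_gene_table <- function() {
  gene_table(character(), character(), integer(), integer(), character())
}

#' Contig constructor
#' @param contig_id text id.
#' @param length contig length in base pairs.
#' @param genes gene table (rows for this contig), sorted by start.
#' @return list of class `qs_contig`.
#' @export
qs_contig <- function(contig_id, length, genes = empty_gene_table()) {
  length <- as.integer(length)
  if (nrow(genes) && any(genes$end > length)) {
    stop("gene coordinates exceed contig length on ", contig_id,
         call. = FALSE)
  }
  structure(list(contig_id = contig_id, length = length,
                 genes = sort_genes(genes)),
            class = "qs_contig")
}

#' Genome constructor
#' @param genome_id text id.
#' @param contigs list of [qs_contig()] objects.
#' @param assembly_status `"complete"` or `"draft"`.
#' @return list of class `qs_genome`.
#' @export
qs_genome <- function(genome_id, contigs,
                      assembly_status = c("complete", "draft")) {
  assembly_status <- match.arg(assembly_status)
  ids <- vapply(contigs, `[[`, "", "contig_id")
  if (anyDuplicated(ids)) stop("duplicate contig ids", call. = FALSE)
  names(contigs) <- ids
  structure(list(genome_id = genome_id, contigs = contigs,
                 assembly_status = assembly_status),
            class = "qs_genome")
}

#' All genes of a genome as one table
#' @param genome a `qs_genome`.
#' @return gene table with rows from every contig.
#' @export
genome_genes <- function(genome) {
  out <- do.call(rbind, lapply(genome$contigs, `[[`, "genes"))
  if (is.null(out)) out <- empty_gene_table()
  rownames(out) <- NULL
  out
}

translate_cds <- function(dna, start, end, strand) {
  sub <- Biostrings::subseq(dna, start, end)
  if (strand == "-") sub <- Biostrings::reverseComplement(sub)
  aa <- as.character(Biostrings::translate(
    sub, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

#' Read an annotated genome
#'
#' Supports two standard encodings of NCBI-style annotation: GFF3 plus FASTA,
#' or a GenBank flat file.  All CDS features become gene records; protein
#' sequences are taken from the annotation (protein FASTA or /translation
#' qualifier) when present, otherwise translated from the nucleotide sequence
#' with translation table 11.  Both routes yield identical 1-based inclusive
#' coordinates.  CDS features with out-of-bounds coordinates are rejected
#' with a warning, not an error; compound (joined) locations are collapsed to
#' their min start / max end with a warning.
#'
#' @param path for `format = "gff3+fasta"`, either a path prefix (expects
#'   `<prefix>.gff3`, `<prefix>.fna` and optionally `<prefix>.faa`) or a named
#'   character vector with elements `gff`, `dna` and optionally `protein`;
#'   for `format = "genbank"`, the flat-file path.
#' @param format `"gff3+fasta"` or `"genbank"`.
#' @param genome_id genome identifier (defaults to the file base name).
#' @param assembly_status `"complete"` or `"draft"`.
#' @return a `qs_genome`.
#' @export
read_annotated_genome <- function(path,
                                  format = c("gff3+fasta", "genbank"),
                                  genome_id = NULL,
                                  assembly_status = "complete") {
  format <- match.arg(format)
  if (format == "gff3+fasta") {
    read_gff3_fasta(path, genome_id, assembly_status)
  } else {
    read_genbank_flat(path, genome_id, assembly_status)
  }
}

read_gff3_fasta <- function(path, genome_id, assembly_status) {
  if (is.null(names(path))) {
    stopifnot(length(path) == 1L)
    path <- c(gff = paste0(path, ".gff3"), dna = paste0(path, ".fna"),
              protein = paste0(path, ".faa"))
    if (!file.exists(path[["protein"]])) path <- path[c("gff", "dna")]
  }
  for (f in path[c("gff", "dna")]) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  gff <- rtracklayer::readGFF(path[["gff"]])
  dna <- Biostrings::readDNAStringSet(path[["dna"]])
  names(dna) <- sub("\\s.*", "", names(dna))
  prot <- NULL
  if ("protein" %in% names(path)) {
    prot <- Biostrings::readAAStringSet(path[["protein"]])
    names(prot) <- sub("\\s.*", "", names(prot))
  }
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  contigs <- lapply(names(dna), function(cid) {
    clen <- Biostrings::width(dna[cid])
    rows <- cds[as.character(cds$seqid) == cid, , drop = FALSE]
    if (!nrow(rows)) return(qs_contig(cid, clen))
    ids <- as.character(rows$ID)
    if (all(is.na(ids))) ids <- paste0(cid, "_cds", seq_len(nrow(rows)))
    oob <- rows$start < 1L | rows$end > clen
    if (any(oob)) {
      warning("rejecting ", sum(oob), " CDS with out-of-bounds coordinates ",
              "on ", cid, ": ", paste(ids[oob], collapse = ", "),
              call. = FALSE)
      rows <- rows[!oob, , drop = FALSE]
      ids <- ids[!oob]
    }
    if (!nrow(rows)) return(qs_contig(cid, clen))
    product <- if ("product" %in% names(rows)) {
      as.character(rows$product)
    } else rep("", nrow(rows))
    product[is.na(product)] <- ""
    pseq <- vapply(seq_len(nrow(rows)), function(i) {
      id <- ids[i]
      if (!is.null(prot) && id %in% names(prot)) {
        return(as.character(prot[[id]]))
      }
      tryCatch(
        translate_cds(dna[[cid]], rows$start[i], rows$end[i],
                      as.character(rows$strand[i])),
        error = function(e) NA_character_)
    }, character(1))
    qs_contig(cid, clen,
              gene_table(ids, cid, rows$start, rows$end,
                         as.character(rows$strand), product, pseq))
  })
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path[["gff"]]))
  }
  qs_genome(genome_id, contigs, assembly_status)
}

#' Write a gene table to a TSV file
#'
#' One row per gene with the fixed, documented columns
#' `gene_id  contig_id  start  end  strand  product  protein_seq
#' is_hypothetical`.  [read_gene_table()] reproduces the table exactly.
#'
#' @param genes gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  write_tsv_table(genes[, GENE_TABLE_COLS, drop = FALSE], path)
}

#' Read a gene table written by [write_gene_table()]
#' @param path TSV path.
#' @return gene table.
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_table(path)
  if (!nrow(df)) return(empty_gene_table())
  df$product[is.na(df$product)] <- ""
  gene_table(df$gene_id, df$contig_id, df$start, df$end, df$strand,
             df$product, df$protein_seq)
}
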