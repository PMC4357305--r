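# Minimal GenBank flat-file reader.  Only what the gene-record model needs:
# LOCUS (contig id + length), CDS features with location, /locus_tag,
# /product and /translation qualifiers, and the ORIGIN sequence (used to
# translate CDS lacking a /translation).  No installed R package parses
# local GenBank flat files, hence this reader.

parse_gb_location <- function(loc, feature_label) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  joined <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    joined <- TRUE
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 1L) {
    stop("unparseable location for ", feature_label, ": ", loc, call. = FALSE)
  }
  if (joined) {
    warning("compound (joined) CDS location collapsed to min..max for ",
            feature_label, call. = FALSE)
  }
  list(start = min(nums), end = max(nums), strand = strand)
}

read_genbank_flat <- function(path, genome_id = NULL,
                              assembly_status = "complete") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  rec_starts <- grep("^LOCUS", lines)
  if (!length(rec_starts)) {
    stop("malformed GenBank file (no LOCUS line): ", path, call. = FALSE)
  }
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  contigs <- lapply(seq_along(rec_starts), function(r) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    locus <- strsplit(trimws(rec[1]), "[[:space:]]+")[[1]]
    cid <- locus[2]
    clen <- suppressWarnings(as.integer(locus[3]))
    # ORIGIN block -> contig sequence
    oi <- grep("^ORIGIN", rec)
    dna <- NULL
    if (length(oi)) {
      seq_lines <- rec[(oi[1] + 1L):length(rec)]
      seq_lines <- seq_lines[!grepl("^//", seq_lines)]
      s <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
      if (nzchar(s)) dna <- Biostrings::DNAString(s)
    }
    if (is.na(clen) && !is.null(dna)) clen <- length(dna)
    fi <- grep("^FEATURES", rec)
    genes <- empty_gene_table()
    if (length(fi)) {
      fend <- if (length(oi)) oi[1] - 1L else length(rec)
      feat <- rec[(fi[1] + 1L):fend]
      # feature keys start at column 6; qualifiers/continuations at column 22
      key_idx <- grep("^     [^ ]", feat)
      if (length(key_idx)) {
        blocks <- Map(function(a, b) feat[a:b], key_idx,
                      c(key_idx[-1] - 1L, length(feat)))
        cds_blocks <- Filter(function(b) {
          grepl("^     CDS[[:space:]]", b[1])
        }, blocks)
        n <- 0L
        rows <- lapply(cds_blocks, function(b) {
          n <<- n + 1L
          # location may wrap onto continuation lines before first qualifier
          qual_start <- grep("^\\s+/", b)[1]
          loc_lines <- if (is.na(qual_start)) b else b[seq_len(qual_start - 1L)]
          loc <- gsub("\\s", "", paste(sub("^     CDS", "", loc_lines),
                                       collapse = ""))
          quals <- if (is.na(qual_start)) character() else
            b[qual_start:length(b)]
          qtext <- paste(trimws(quals), collapse = "\n")
          get_qual <- function(name, collapse_ws = TRUE) {
            m <- regmatches(qtext, regexpr(
              paste0("/", name, "=\"[^\"]*\""), qtext))
            if (!length(m)) return(NA_character_)
            v <- sub(paste0("^/", name, "=\""), "", sub("\"$", "", m))
            gsub(if (collapse_ws) "\\s+" else "\n", if (collapse_ws) " " else "",
                 v)
          }
          lt <- get_qual("locus_tag")
          if (is.na(lt)) lt <- get_qual("protein_id")
          if (is.na(lt)) lt <- paste0(cid, "_cds", n)
          label <- paste0(cid, "/", lt)
          pos <- parse_gb_location(loc, label)
          product <- get_qual("product")
          if (is.na(product)) product <- ""
          transl <- get_qual("translation")
          if (!is.na(transl)) transl <- gsub("\\s", "", transl)
          data.frame(gene_id = lt, start = pos$start, end = pos$end,
                     strand = pos$strand, product = product,
                     translation = transl, stringsAsFactors = FALSE)
        })
        rows <- do.call(rbind, rows)
        if (!is.null(rows) && nrow(rows)) {
          oob <- rows$start < 1L | (!is.na(clen) & rows$end > clen)
          if (any(oob)) {
            warning("rejecting ", sum(oob),
                    " CDS with out-of-bounds coordinates on ", cid, ": ",
                    paste(rows$gene_id[oob], collapse = ", "), call. = FALSE)
            rows <- rows[!oob, , drop = FALSE]
          }
          if (nrow(rows)) {
            pseq <- vapply(seq_len(nrow(rows)), function(i) {
              if (!is.na(rows$translation[i])) return(rows$translation[i])
              if (is.null(dna)) return(NA_character_)
              tryCatch(
                translate_cds(dna, rows$start[i], rows$end[i],
                              rows$strand[i]),
                error = function(e) NA_character_)
            }, character(1))
            genes <- gene_table(rows$gene_id, cid, rows$start, rows$end,
                                rows$strand, rows$product, pseq)
          }
        }
      }
    }
    qs_contig(cid, clen, genes)
  })
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  qs_genome(genome_id, contigs, assembly_status)
}
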