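# Neighbor-joining cladogram and clade extraction.  NJ is the classic
# Saitou-Nei agglomeration with deterministic tie-breaking (lexicographically
# smallest id pair wins), so trees are reproducible bit-for-bit; negative
# branch-length estimates are clamped to zero, the standard practice.

#' Build a neighbor-joining tree
#'
#' @param d symmetric distance matrix with >= 3 taxa; dimnames are taxon ids.
#' @return an [ape::read.tree()] `phylo` object (unrooted; the root
#'   trifurcation is a representation artifact).
#' @export
build_nj_tree <- function(d) {
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric",
                                    call. = FALSE)
  n <- nrow(d)
  if (n < 3) stop("neighbor-joining requires >= 3 taxa", call. = FALSE)
  ids <- rownames(d)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  # working copies; node labels carry newick fragments as they agglomerate
  labels <- ids
  newick <- ids
  # first id (lexicographic) of each cluster, for tie-breaking
  first_id <- ids
  dm <- d
  clamp <- function(x) {
    if (x < 0) {
      message("negative NJ branch length clamped to zero")
      0
    } else x
  }
  while (nrow(dm) > 3) {
    r <- nrow(dm)
    R <- rowSums(dm)
    Q <- (r - 2) * dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(first_id[cand[k, 1]], first_id[cand[k, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- clamp(dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(dm[i, j] - li)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], li, newick[j], lj)
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    newick <- c(newick[keep], merged)
    first_id <- c(first_id[keep], min(first_id[c(i, j)]))
    rn <- c(rownames(dm)[keep], paste0("(", rownames(dm)[i], ")"))
    dimnames(dm2) <- list(rn, rn)
    dm <- dm2
  }
  # final three-point join (closed-form branch lengths)
  l1 <- clamp((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2)
  l2 <- clamp((dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2)
  l3 <- clamp((dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 newick[1], l1, newick[2], l2, newick[3], l3)
  ape::read.tree(text = txt)
}

#' Annotate tree leaves with census labels
#'
#' Rewrites tip labels as `id|topology|motif|cys` for annotated Newick
#' export.
#'
#' @param tree `phylo` object with gene-id tips.
#' @param topology named character vector gene_id -> topology label.
#' @param motif named character vector gene_id -> motif label.
#' @param cys named integer vector gene_id -> total cysteine count.
#' @return the tree with rewritten tip labels.
#' @export
annotate_tree_leaves <- function(tree, topology = NULL, motif = NULL,
                                 cys = NULL) {
  g <- function(v, id) if (is.null(v) || is.na(v[id] %||% NA)) "NA" else v[[id]]
  tree$tip.label <- vapply(tree$tip.label, function(id) {
    paste(id, g(topology, id), g(motif, id), g(cys, id), sep = "|")
  }, character(1))
  tree
}

#' Extract clades by a within-clade distance threshold
#'
#' Clades are maximal complete subtrees whose leaf-to-leaf path lengths are
#' all `<= max_within_distance`.  The unrooted NJ tree is midpoint-rooted
#' first (the root trifurcation of the NJ representation is an arbitrary
#' placement that can fall inside a tight cluster); the recursion then
#' descends from the root, emitting a subtree as soon as it satisfies the
#' threshold, so the returned clades are disjoint and cover all leaves.
#'
#' @param tree `phylo` object with branch lengths.
#' @param max_within_distance maximum allowed leaf-leaf path distance within
#'   a clade, in branch-length units.
#' @return named list of character vectors (leaf ids per clade), named
#'   `clade1`, `clade2`, ... in depth-first order.
#' @export
extract_clades <- function(tree, max_within_distance) {
  if (length(tree$tip.label) > 2) {
    tree <- phangorn::midpoint(tree)
  }
  pd <- stats::cophenetic(tree)
  ntips <- length(tree$tip.label)
  root <- ntips + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntips) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  clades <- list()
  walk <- function(node) {
    tips <- tips_under(node)
    labs <- tree$tip.label[tips]
    if (length(tips) == 1L ||
        max(pd[labs, labs]) <= max_within_distance) {
      clades[[length(clades) + 1L]] <<- labs
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) walk(ch)
  }
  walk(root)
  names(clades) <- paste0("clade", seq_along(clades))
  clades
}

#' Clade membership as a data frame
#' @param clades list from [extract_clades()].
#' @return data frame `clade_id`, `gene_id`.
#' @export
clades_as_table <- function(clades) {
  if (!length(clades)) {
    return(data.frame(clade_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(clade_id = rep(names(clades), lengths(clades)),
             gene_id = unlist(clades, use.names = FALSE),
             stringsAsFactors = FALSE)
}
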