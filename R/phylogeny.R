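## Three-way ortholog concatenation, pairwise distances and a
## neighbor-joining tree.

#' Three-way ortholog triples from two pair lists sharing species A
#'
#' @param pairs_ab,pairs_ac data.frames with columns `gene_a` and
#'   `gene_b` / `gene_c` (the shared species is `gene_a`).
#' @return data.frame `gene_a`, `gene_b`, `gene_c`; A-genes paired with
#'   more than one partner in either list are dropped.
#' @export
threeway_orthologs <- function(pairs_ab, pairs_ac) {
  if (!"gene_c" %in% names(pairs_ac)) names(pairs_ac)[names(pairs_ac) == "gene_b"] <- "gene_c"
  ok_ab <- pairs_ab[!(pairs_ab$gene_a %in% pairs_ab$gene_a[duplicated(pairs_ab$gene_a)]), ]
  ok_ac <- pairs_ac[!(pairs_ac$gene_a %in% pairs_ac$gene_a[duplicated(pairs_ac$gene_a)]), ]
  out <- merge(ok_ab[, c("gene_a", "gene_b")], ok_ac[, c("gene_a", "gene_c")],
               by = "gene_a")
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concatenate three-way CDS alignments anchored on species A
#'
#' For each triple, the columns kept are those A positions aligned in
#' both pairwise CDS alignments; columns containing a gap (absent from
#' either alignment) or an `N` in any member are removed.  Genes are
#' concatenated in sorted `gene_a` order so the result is independent
#' of input order.
#'
#' @param triples data.frame from [threeway_orthologs()].
#' @param aligned_ab,aligned_ac aligned-region lists (named
#'   `gene_a|gene_b`) from [orthology_stage()].
#' @param seqs named character vector of all transcript sequences.
#' @param labels taxon labels, default `c("A", "B", "C")`.
#' @return list: `seqs` (3 named concatenated strings), `n_col`,
#'   `genes` (data.frame gene/`n_col` per gene), `n_skipped`.
#' @export
build_concatenation <- function(triples, aligned_ab, aligned_ac, seqs,
                                labels = c("A", "B", "C")) {
  triples <- triples[order(triples$gene_a), , drop = FALSE]
  parts <- list(character(0), character(0), character(0))
  genes <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(triples))) {
    ga <- triples$gene_a[i]
    ab <- aligned_ab[[paste(ga, triples$gene_b[i], sep = "|")]]
    ac <- aligned_ac[[paste(ga, triples$gene_c[i], sep = "|")]]
    if (is.null(ab$cds) || is.null(ac$cds)) { n_skipped <- n_skipped + 1L; next }
    common <- intersect(ab$cds$i_a, ac$cds$i_a)
    if (!length(common)) { n_skipped <- n_skipped + 1L; next }
    common <- sort(common)
    ib <- ab$cds$i_b[match(common, ab$cds$i_a)]
    ic <- ac$cds$i_b[match(common, ac$cds$i_a)]
    ba <- substring(seqs[[ga]], common, common)
    bb <- substring(seqs[[triples$gene_b[i]]], ib, ib)
    bc <- substring(seqs[[triples$gene_c[i]]], ic, ic)
    keep <- ba != "N" & bb != "N" & bc != "N"
    if (!any(keep)) { n_skipped <- n_skipped + 1L; next }
    parts[[1]] <- c(parts[[1]], ba[keep])
    parts[[2]] <- c(parts[[2]], bb[keep])
    parts[[3]] <- c(parts[[3]], bc[keep])
    genes[[length(genes) + 1L]] <- data.frame(gene = ga, n_col = sum(keep))
  }
  seqs_out <- stats::setNames(vapply(parts, paste, "", collapse = ""), labels)
  list(seqs = seqs_out, n_col = nchar(seqs_out[[1]]),
       genes = if (length(genes)) do.call(rbind, genes)
             else data.frame(gene = character(0), n_col = integer(0)),
       n_skipped = n_skipped)
}

#' Pairwise distance matrix from a gapless alignment
#'
#' Closed-form distances in substitutions per site: `p` (raw
#' proportion), `K2P` (Kimura two-parameter) or `TN93`
#' (Tamura-Nei), computed with [ape::dist.dna()].
#'
#' @param alignment list from [build_concatenation()], or a named
#'   character vector of equal-length sequences.
#' @param model one of `"p"`, `"K2P"`, `"TN93"` (default).
#' @return symmetric matrix of distances with zero diagonal.
#' @export
pairwise_distance <- function(alignment, model = c("TN93", "K2P", "p")) {
  model <- match.arg(model)
  seqs <- if (is.list(alignment) && !is.null(alignment$seqs)) alignment$seqs else alignment
  if (length(unique(nchar(seqs))) != 1) stopf("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bin <- ape::as.DNAbin(mat)
  ape_model <- c(p = "raw", K2P = "K80", TN93 = "TN93")[[model]]
  d <- as.matrix(ape::dist.dna(bin, model = ape_model, pairwise.deletion = FALSE))
  bad <- which(!is.finite(d) & row(d) != col(d), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("distance undefined (saturation) for pair %s-%s",
          rownames(d)[bad[1, 1]], colnames(d)[bad[1, 2]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; for three taxa the
#' branch lengths solve the three-point linear system exactly.
#' Negative branch lengths are clamped to zero with a warning.
#'
#' @param d symmetric distance matrix with taxon labels.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stopf("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix is not symmetric")
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Path-length (patristic) distances of a tree
#'
#' @param tree an [ape::phylo] tree.
#' @return symmetric matrix of tip-to-tip path lengths.
#' @export
tree_path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}
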