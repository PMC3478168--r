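## Protein-family clustering across species (Markov Cluster algorithm on
## an all-against-all similarity graph) and hypergeometric enrichment of
## annotation terms in the core families.

#' Select translated genes for family clustering
#'
#' Keeps, per gene, the hit with the longest translated span among hits
#' below `evalue_max`, and drops genes whose span is shorter than
#' `min_nt_len` nucleotides.
#'
#' @param transcripts transcript table from [read_fasta()].
#' @param protein_hits translated-search hit table with frames.
#' @param min_nt_len minimum nucleotide span (default 200, about 66 aa).
#' @param evalue_max maximum hit E-value (default 1e-5).
#' @return data.frame: `id`, `species`, `nt_span`, `protein` (translated
#'   sequence of the spanned region).
#' @export
prepare_translations <- function(transcripts, protein_hits,
                                 min_nt_len = 200L, evalue_max = 1e-5) {
  hits <- protein_hits[protein_hits$evalue < evalue_max, , drop = FALSE]
  hits <- hits[hits$query %in% transcripts$id, , drop = FALSE]
  seqv <- stats::setNames(transcripts$seq, transcripts$id)
  spv <- stats::setNames(transcripts$species, transcripts$id)
  rows <- lapply(split(hits, hits$query), function(g) {
    span <- abs(g$q_end - g$q_start) + 1L
    g <- g[which.max(span), , drop = FALSE]
    nt_span <- abs(g$q_end - g$q_start) + 1L
    if (nt_span < min_nt_len) return(NULL)
    s <- seqv[[g$query]]
    lo <- min(g$q_start, g$q_end); hi <- max(g$q_start, g$q_end)
    region <- substr(s, lo, hi)
    if (g$frame < 0) region <- revcomp(region)
    data.frame(id = g$query, species = spv[[g$query]],
               nt_span = nt_span, protein = translate_cds(region),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(id = character(0), species = character(0),
                                      nt_span = integer(0), protein = character(0)))
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the undirected similarity graph from directed hit tables
#'
#' Edge weight is the maximum bitscore over the two directions;
#' self-hits are ignored (MCL self-loops are added internally).
#'
#' @param hits one hit table, or a list of tables, covering the
#'   all-against-all search.
#' @param nodes data.frame with columns `id` and `species` naming every
#'   graph node (isolated nodes allowed).
#' @return list with `nodes` and `edges` (`from`, `to`, `weight`).
#' @export
similarity_graph <- function(hits, nodes) {
  if (is.data.frame(hits)) hits <- list(hits)
  h <- do.call(rbind, lapply(hits, function(x)
    x[, c("query", "subject", "bitscore"), drop = FALSE]))
  h <- h[h$query %in% nodes$id & h$subject %in% nodes$id &
         h$query != h$subject, , drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$query, h$subject); b <- pmax(h$query, h$subject)
    key <- paste(a, b, sep = "\r")
    w <- tapply(h$bitscore, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 2),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  if (any(edges$weight <= 0)) stopf("non-positive edge weight")
  list(nodes = nodes[order(nodes$id), , drop = FALSE], edges = edges)
}

## Connected components of an undirected adjacency pattern (logical or
## numeric matrix); returns an integer membership vector.
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(adj[v, ] & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Markov Cluster (MCL) protein families
#'
#' Builds the column-stochastic transition matrix from edge weights with
#' self-loops set to each node's maximum incident weight, then iterates
#' expansion (matrix squaring) and inflation (entrywise power
#' `inflation`, column renormalisation) with pruning of entries below
#' `prune` until the largest entry change falls below `tol` or
#' `max_iter` iterations.  Clusters are the connected components of the
#' limit matrix's support.  The result is invariant to node input order
#' and to uniform scaling of the weights.
#'
#' @param graph list from [similarity_graph()].
#' @param inflation inflation exponent (> 1; default 1.6).
#' @param tol convergence tolerance on entries (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @param prune entries below this are zeroed each iteration
#'   (default 1e-12).
#' @return data.frame: `id`, `species`, `family` (integer label;
#'   families numbered by their first member in sorted id order), plus
#'   attribute `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 1.6, tol = 1e-8,
                        max_iter = 200L, prune = 1e-12) {
  if (inflation <= 1) stopf("inflation must be > 1")
  ids <- sort(graph$nodes$id)
  n <- length(ids)
  if (n == 0) stopf("empty graph")
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, ids); j <- match(graph$edges$to, ids)
    M[cbind(i, j)] <- graph$edges$weight
    M[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1               # isolated nodes
  diag(M) <- loop
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                     # expansion
    M2 <- M2 ^ inflation              # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within the iteration cap")
  comp <- components_of(M > 0 | t(M) > 0)
  out <- data.frame(id = ids, family = comp, stringsAsFactors = FALSE)
  out <- merge(out, graph$nodes, by = "id", sort = TRUE)
  out <- out[order(out$id), c("id", "species", "family")]
  rownames(out) <- NULL
  attr(out, "converged") <- converged
  out
}

#' Species-composition (Venn) counts of protein families
#'
#' @param families data.frame from [mcl_cluster()].
#' @return list with `counts` (one row per non-empty species
#'   composition, `core` flagging families spanning all species) and
#'   `family_table` (per-family species membership and core flag).
#' @export
classify_families <- function(families) {
  species <- sort(unique(families$species))
  per_fam <- split(families$species, families$family)
  comp <- vapply(per_fam, function(s) paste(sort(unique(s)), collapse = "+"), "")
  fam_tab <- data.frame(family = as.integer(names(per_fam)),
                        n_members = lengths(per_fam),
                        composition = comp,
                        is_core = comp == paste(species, collapse = "+"),
                        stringsAsFactors = FALSE)
  counts <- as.data.frame(table(composition = comp), stringsAsFactors = FALSE)
  names(counts)[2] <- "n_families"
  counts$core <- counts$composition == paste(species, collapse = "+")
  list(counts = counts, family_table = fam_tab[order(fam_tab$family), ])
}

#' Hypergeometric enrichment of annotation terms in a gene subset
#'
#' For each term, the p-value is the upper tail
#' `P(X >= k)` of a hypergeometric draw: population = annotated genes in
#' `all_genes`, successes = annotated genes carrying the term, draws =
#' annotated genes in `core_genes`.  Terms with `p < alpha` are
#' reported; a Bonferroni-adjusted column is emitted alongside the raw
#' p-values.
#'
#' @param core_genes character vector (the core-family genes).
#' @param all_genes character vector (the clustered population).
#' @param annotations data.frame with columns `gene`, `term`.
#' @param alpha raw p-value cutoff (default 1e-5).
#' @param species optional named vector gene -> species for per-species
#'   member counts.
#' @return data.frame of enriched terms: term, per-population counts,
#'   `p`, `p_bonferroni`, and per-species core counts when `species`
#'   is given.
#' @export
hypergeom_enrichment <- function(core_genes, all_genes, annotations,
                                 alpha = 1e-5, species = NULL) {
  annotations <- annotations[annotations$gene %in% all_genes, , drop = FALSE]
  annotated <- unique(annotations$gene)
  pop <- length(annotated)
  core_annot <- intersect(core_genes, annotated)
  ndraw <- length(core_annot)
  terms <- unique(annotations$term)
  n_tests <- length(terms)
  rows <- lapply(terms, function(tm) {
    carriers <- unique(annotations$gene[annotations$term == tm])
    K <- length(carriers)
    k <- length(intersect(carriers, core_annot))
    p <- stats::phyper(k - 1, K, pop - K, ndraw, lower.tail = FALSE)
    data.frame(term = tm, core_with_term = k, core_annotated = ndraw,
               all_with_term = K, all_annotated = pop, p = p,
               p_bonferroni = min(1, p * n_tests), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p < alpha, , drop = FALSE]
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (!is.null(species) && nrow(out)) {
    for (sp in sort(unique(species))) {
      out[[paste0("core_", sp)]] <- vapply(out$term, function(tm) {
        carriers <- unique(annotations$gene[annotations$term == tm])
        sum(species[intersect(carriers, core_annot)] == sp)
      }, integer(1))
    }
  }
  rownames(out) <- NULL
  out
}
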