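## End-to-end orchestration: simulate (optional) -> expression ->
## orthology -> divergence -> selection -> families -> phylogeny ->
## snp -> reports.  The report bundle is a pure function of
## (config, inputs); all randomness derives from config$seed.

## Reconstruct the gapless codon-aligned CDS strings of a pair from its
## aligned columns.
aligned_cds_strings <- function(aln, seq_a, seq_b) {
  cds <- aln$cds
  list(a = paste(substring(seq_a, cds$i_a, cds$i_a), collapse = ""),
       b = paste(substring(seq_b, cds$i_b, cds$i_b), collapse = ""))
}

run_stage <- function(name, expr, quiet = FALSE) {
  od_log(name, "start", quiet = quiet)
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full comparative-transcriptome pipeline
#'
#' In simulate mode a complete synthetic dataset with known ground
#' truth is generated first; otherwise `manifest` must name the input
#' files (`fasta_A/B/C`, `tx_A_vs_B`, `tx_B_vs_A`, `tx_A_vs_C`,
#' `tx_C_vs_A`, `prot_A/B/C`, optionally `sam_A` and `annotations`).
#' Stage order: expression, orthology (A-B and A-C), divergence,
#' selection, families, phylogeny, SNP, reports.
#'
#' @param out_dir run directory (created).
#' @param config settings list (see [default_config()]).
#' @param manifest named list of input paths, or `NULL` to simulate.
#' @param params simulation parameters (simulate mode only); defaults
#'   to `evol_params(seed = config$seed)`.
#' @param allow_partial skip the expression and SNP stages when no SAM
#'   input is available instead of failing.
#' @return invisibly, a list of result objects and written paths.
#' @export
run_all <- function(out_dir, config = default_config(), manifest = NULL,
                    params = NULL, allow_partial = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  quiet <- isTRUE(config$quiet)
  simulate <- is.null(manifest)
  truth <- NULL
  if (simulate) {
    if (is.null(params)) params <- evol_params(seed = config$seed)
    ds <- run_stage("simulate",
                    simulate_dataset(params, file.path(out_dir, "sim")),
                    quiet)
    manifest <- ds$files
    truth <- ds$truth
  }
  need <- c("fasta_A", "fasta_B", "fasta_C", "tx_A_vs_B", "tx_B_vs_A",
            "tx_A_vs_C", "tx_C_vs_A", "prot_A", "prot_B", "prot_C")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) stopf("manifest missing input: %s", missing[1])

  seqs_a <- read_fasta(manifest$fasta_A, "A")
  seqs_b <- read_fasta(manifest$fasta_B, "B")
  seqs_c <- read_fasta(manifest$fasta_C, "C")
  all_seqs <- stats::setNames(c(seqs_a$seq, seqs_b$seq, seqs_c$seq),
                              c(seqs_a$id, seqs_b$id, seqs_c$id))
  tx_ab <- parse_blast_tab(manifest$tx_A_vs_B)
  tx_ba <- parse_blast_tab(manifest$tx_B_vs_A)
  tx_ac <- parse_blast_tab(manifest$tx_A_vs_C)
  tx_ca <- parse_blast_tab(manifest$tx_C_vs_A)
  prot <- lapply(manifest[c("prot_A", "prot_B", "prot_C")], parse_blast_tab)
  names(prot) <- c("A", "B", "C")
  annotations <- if (!is.null(manifest$annotations))
    utils::read.delim(manifest$annotations, stringsAsFactors = FALSE) else NULL
  results <- list(truth = truth, config = config)

  ## --- expression ---
  have_sam <- !is.null(manifest$sam_A)
  if (!have_sam && !allow_partial) stopf("manifest missing input: sam_A")
  if (have_sam) {
    sam_a <- parse_sam_min(manifest$sam_A)
    expr <- run_stage("expression", {
      lens <- stats::setNames(nchar(seqs_a$seq), seqs_a$id)
      expression_stage(sam_a, lens, low = config$rpkm_low, high = config$rpkm_high)
    }, quiet)
    results$expression <- expr
    results$read_share <- read_share_by_class(expr)
    write_tsv_report(expr, names(expr), file.path(out_dir, "expression.tsv"))
    write_tsv_report(results$read_share, names(results$read_share),
                     file.path(out_dir, "expression_classes.tsv"))
  } else {
    warning("no SAM input: expression stage skipped")
  }

  ## --- orthology (A-B and A-C) ---
  orth_ab <- run_stage("orthology_AB",
    orthology_stage(tx_ab, tx_ba, prot$A, prot$B, seqs_a, seqs_b, config = config),
    quiet)
  orth_ac <- run_stage("orthology_AC",
    orthology_stage(tx_ac, tx_ca, prot$A, prot$C, seqs_a, seqs_c, config = config),
    quiet)
  results$orthology <- list(AB = orth_ab, AC = orth_ac)
  od_log("orthology", sprintf("A-B pairs: %d; A-C pairs: %d",
                              nrow(orth_ab$pairs), nrow(orth_ac$pairs)), quiet = quiet)
  write_tsv_report(orth_ab$pairs, names(orth_ab$pairs),
                   file.path(out_dir, "ortholog_pairs_AB.tsv"))
  write_tsv_report(orth_ac$pairs, names(orth_ac$pairs),
                   file.path(out_dir, "ortholog_pairs_AC.tsv"))

  ## --- divergence (A-B) ---
  div <- run_stage("divergence", {
    keys <- names(orth_ab$aligned)
    tallies <- lapply(keys, function(k) {
      p <- orth_ab$partitions[[k]]
      count_substitutions(orth_ab$aligned[[k]], p$a$seq, p$b$seq)
    })
    summary <- summarize_divergence(tallies)
    hom <- pair_homology(tallies, pair_ids = keys)
    list(summary = summary, homology = hom, tallies = tallies)
  }, quiet)
  results$divergence <- div
  write_tsv_report(div$summary, names(div$summary),
                   file.path(out_dir, "divergence_summary.tsv"))
  write_tsv_report(div$homology$pairs, names(div$homology$pairs),
                   file.path(out_dir, "pair_homology.tsv"))
  write_tsv_report(div$homology$stats, names(div$homology$stats),
                   file.path(out_dir, "pair_homology_stats.tsv"))
  if (!is.null(annotations)) {
    hom_genes <- data.frame(
      gene = gene_of_id(vapply(strsplit(div$homology$pairs$pair, "|", fixed = TRUE),
                               `[`, "", 1)),
      homology_pct = div$homology$pairs$homology_pct)
    cats <- data.frame(gene = annotations$gene, category = annotations$term)
    cat_id <- group_identity_by_category(hom_genes, cats,
                                         min_members = config$min_category_members)
    results$category_identity <- cat_id
    write_tsv_report(cat_id, names(cat_id),
                     file.path(out_dir, "category_identity.tsv"))
  }

  ## --- selection (Ka/Ks on A-B CDS) ---
  kaks <- run_stage("selection", {
    keys <- names(orth_ab$aligned)
    cds_pairs <- lapply(keys, function(k) {
      p <- orth_ab$partitions[[k]]
      aligned_cds_strings(orth_ab$aligned[[k]], p$a$seq, p$b$seq)
    })
    names(cds_pairs) <- keys
    kaks_table(cds_pairs)
  }, quiet)
  results$kaks <- kaks
  write_tsv_report(kaks, names(kaks), file.path(out_dir, "kaks.tsv"))

  ## --- families ---
  fam <- run_stage("families", {
    tx_all <- rbind(seqs_a, seqs_b, seqs_c)
    nodes <- prepare_translations(tx_all, do.call(rbind, prot),
                                  min_nt_len = config$min_len,
                                  evalue_max = config$prot_evalue)
    graph <- similarity_graph(list(tx_ab, tx_ba, tx_ac, tx_ca),
                              nodes[, c("id", "species")])
    fams <- mcl_cluster(graph, inflation = config$inflation)
    venn <- classify_families(fams)
    core_fams <- venn$family_table$family[venn$family_table$is_core]
    core_genes <- unique(gene_of_id(fams$id[fams$family %in% core_fams]))
    all_genes <- unique(gene_of_id(fams$id))
    enrich <- if (!is.null(annotations)) {
      hypergeom_enrichment(core_genes, all_genes, annotations,
                           alpha = config$enrich_alpha)
    } else NULL
    list(families = fams, venn = venn, core_genes = core_genes,
         enrichment = enrich)
  }, quiet)
  results$families <- fam
  write_tsv_report(fam$families, names(fam$families),
                   file.path(out_dir, "families.tsv"))
  write_tsv_report(fam$venn$counts, names(fam$venn$counts),
                   file.path(out_dir, "venn_counts.tsv"))
  if (!is.null(fam$enrichment)) {
    write_tsv_report(fam$enrichment, names(fam$enrichment),
                     file.path(out_dir, "enrichment.tsv"))
  }

  ## --- phylogeny ---
  phylo <- run_stage("phylogeny", {
    triples <- threeway_orthologs(orth_ab$pairs[, c("gene_a", "gene_b")],
                                  orth_ac$pairs[, c("gene_a", "gene_b")])
    conc <- build_concatenation(triples, orth_ab$aligned, orth_ac$aligned,
                                all_seqs)
    d <- pairwise_distance(conc, model = config$distance_model)
    tree <- nj_tree(d)
    list(triples = triples, concatenation = conc, distances = d, tree = tree)
  }, quiet)
  results$phylogeny <- phylo
  write_newick(phylo$tree, file.path(out_dir, "tree.nwk"))
  dm <- as.data.frame(phylo$distances)
  dm <- cbind(taxon = rownames(dm), dm)
  write_tsv_report(dm, names(dm), file.path(out_dir, "distances.tsv"))

  ## --- snp ---
  if (have_sam) {
    snps <- run_stage("snp", {
      part_a <- lapply(orth_ab$partitions, `[[`, "a")
      genes <- vapply(strsplit(names(part_a), "|", fixed = TRUE), `[`, "", 1)
      ivs <- data.frame(gene = genes,
                        cds_start = vapply(part_a, `[[`, 0L, "cds_start"),
                        cds_end = vapply(part_a, `[[`, 0L, "cds_end"),
                        stringsAsFactors = FALSE)
      ivs <- ivs[!duplicated(ivs$gene), , drop = FALSE]
      snp_stage(sam_a, ivs, all_seqs, config = config)
    }, quiet)
    results$snps <- snps
    write_tsv_report(snps, names(snps), file.path(out_dir, "snps.tsv"))
  } else {
    warning("no SAM input: snp stage skipped")
  }

  ## --- manifest ---
  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE), "MANIFEST.tsv"))
  writeLines(c("file", outputs), file.path(out_dir, "MANIFEST.tsv"))
  od_log("done", sprintf("%d files written to %s", length(outputs), out_dir),
         quiet = quiet)
  invisible(results)
}
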