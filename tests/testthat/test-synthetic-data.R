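test_that("ancestors are codon-structured and deterministic", {
  p <- evol_params(n_genes = 5, cds_len_range = c(300L, 300L), seed = 11)
  anc <- simulate_ancestors(p)
  expect_equal(nrow(anc$genes), 5L)
  for (i in 1:5) {
    g <- anc$genes[i, ]
    cds <- substr(g$seq, g$cds_start, g$cds_end)
    expect_equal(g$cds_len, 300L)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, 298, 300) %in% c("TAA", "TAG", "TGA"))
    stops <- orthodiv:::inframe_stops(cds)
    expect_equal(stops, 298L)           # the terminal stop only
  }
  anc2 <- simulate_ancestors(p)
  expect_identical(anc$genes, anc2$genes)
  expect_error(evol_params(cds_len_range = c(900L, 300L)), "degenerate")
})

test_that("zero branch lengths give identical copies of each ancestor", {
  p <- evol_params(n_genes = 4, t_A = 0, t_B = 0, t_C = 0, seed = 2)
  tr <- evolve_triple(simulate_ancestors(p))
  anc <- tr$truth$regions
  for (sp in c("A", "B", "C")) {
    expect_equal(tr$species[[sp]]$seq, anc$seq)
  }
})

test_that("full constraint suppresses all nondegenerate-site changes", {
  p <- evol_params(n_genes = 6, t_A = 0.05, t_B = 0, t_C = 0,
                   f_nd = 0, f_ns = 0, cpg_mult = 1, seed = 13)
  tr <- evolve_triple(simulate_ancestors(p))
  anc <- tr$truth$regions
  deg <- orthodiv:::degeneracy_table()
  for (i in seq_len(nrow(anc))) {
    a <- strsplit(anc$seq[i], "")[[1]]
    e <- strsplit(tr$species$A$seq[i], "")[[1]]
    for (pos in seq(anc$cds_start[i], anc$cds_end[i])) {
      ph <- (pos - anc$cds_start[i]) %% 3
      cod <- paste(a[(pos - ph):(pos - ph + 2)], collapse = "")
      if (!(cod %in% rownames(deg))) next
      lab <- deg[cod, ph + 1]
      if (lab == "nd") expect_equal(e[pos], a[pos])
    }
  }
})

test_that("evolution and paralog planting are seed-deterministic", {
  p <- evol_params(n_genes = 10, seed = 5)
  t1 <- plant_paralogs(evolve_triple(simulate_ancestors(p)))
  t2 <- plant_paralogs(evolve_triple(simulate_ancestors(p)))
  expect_identical(t1$species, t2$species)
  expect_identical(t1$truth$paralogs, t2$truth$paralogs)
})

test_that("paralog planting duplicates the requested fraction", {
  p0 <- evol_params(n_genes = 10, paralog_frac = 0, seed = 5)
  t0 <- plant_paralogs(evolve_triple(simulate_ancestors(p0)))
  expect_equal(nrow(t0$truth$paralogs), 0L)
  expect_equal(sum(vapply(t0$species, nrow, 0L)), 30L)

  p <- evol_params(n_genes = 100, paralog_frac = 0.1, seed = 5)
  tp <- plant_paralogs(evolve_triple(simulate_ancestors(p)))
  expect_equal(nrow(tp$truth$paralogs), 10L)
  expect_equal(sum(vapply(tp$species, nrow, 0L)), 310L)
  expect_true(all(grepl("_par$", tp$truth$paralogs$paralog_id)))
})

test_that("simulated reads are byte-deterministic and carry planted SNPs", {
  p <- evol_params(n_genes = 6, het_rate = 2, mean_depth = 60, seed = 21)
  tr <- evolve_triple(simulate_ancestors(p))
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  r1 <- simulate_reads(tr, "A", f1)
  r2 <- simulate_reads(tr, "A", f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(nrow(r1$snps), 0L)

  # alternate-allele counts behave binomially at the planted frequency
  sam <- parse_sam_min(f1)
  reg <- tr$truth$regions
  for (i in seq_len(min(5, nrow(r1$snps)))) {
    s <- r1$snps[i, ]
    reads <- sam[sam$target_id == s$id, ]
    covering <- reads$pos <= s$pos & reads$pos + nchar(reads$seq) - 1L >= s$pos
    depth <- sum(covering)
    if (depth == 0) next
    alt_n <- sum(substring(reads$seq[covering],
                           s$pos - reads$pos[covering] + 1L,
                           s$pos - reads$pos[covering] + 1L) == s$alt)
    # 4 SD binomial window around freq 0.5
    expect_lt(abs(alt_n - depth * 0.5), 4 * sqrt(depth * 0.25) + 1)
  }
})

test_that("similarity tables reflect true homologies and paralogs compete", {
  p <- evol_params(n_genes = 10, t_A = 0, t_B = 0, t_C = 0,
                   paralog_frac = 0.2, spurious_rate = 0, seed = 31)
  tr <- plant_paralogs(evolve_triple(simulate_ancestors(p)))
  paths <- simulate_similarity_tables(tr, withr::local_tempdir())
  ab <- parse_blast_tab(paths$tx_A_vs_B)
  # zero divergence: original copies hit at 100% identity
  orig <- ab[!grepl("_par$", ab$query), ]
  expect_true(all(orig$pct_identity == 100))
  # hit count = true homologies + paralog competition, no spurious rows
  n_par_ab <- sum(tr$truth$paralogs$species %in% c("A", "B"))
  expect_equal(nrow(ab), 10L + n_par_ab)
  # a planted paralog produces two hits for the same subject's query group
  par_b <- tr$truth$paralogs[tr$truth$paralogs$species == "B", ]
  if (nrow(par_b)) {
    g <- par_b$gene[1]
    hits_g <- ab[ab$query == paste0("A_", g), ]
    expect_equal(sort(hits_g$subject),
                 sort(c(paste0("B_", g), par_b$paralog_id[par_b$gene == g])))
  }
  # protein tables carry the frame column
  pa <- parse_blast_tab(paths$prot_A)
  expect_true(all(pa$frame >= 1))
  expect_equal(nrow(pa), nrow(tr$species$A))
})

test_that("annotation enrichment planting is detectable and controlled", {
  genes <- sprintf("g%03d", 1:600)
  core <- genes[1:200]
  # null table: no planted term reaches the 1e-5 cutoff in 50 replicates
  false_pos <- 0
  for (s in 1:50) {
    ann <- simulate_annotation_tables(genes, core, n_terms = 20,
                                      enriched_terms = character(0), seed = s)
    hits <- hypergeom_enrichment(core, genes, ann, alpha = 1e-5)
    if (nrow(hits) > 0) false_pos <- false_pos + 1
  }
  expect_lte(false_pos, 1)

  # a 5x planted term is found in at least 95% of replicates
  found <- 0
  for (s in 1:40) {
    ann <- simulate_annotation_tables(genes, core, n_terms = 20,
                                      enriched_terms = "GO:0007",
                                      enrich_mult = 5, seed = s + 1000)
    hits <- hypergeom_enrichment(core, genes, ann, alpha = 1e-5)
    if ("GO:0007" %in% hits$term) found <- found + 1
  }
  expect_gte(found / 40, 0.95)

  # single term carried by everyone cannot be enriched
  ann1 <- simulate_annotation_tables(genes, core, n_terms = 1, seed = 3)
  p1 <- hypergeom_enrichment(core, genes, ann1, alpha = 1.1)
  expect_equal(p1$p, 1.0)
})
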