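mk_graph <- function(edges, ids = NULL, species = "A") {
  if (is.null(ids)) ids <- sort(unique(c(edges$from, edges$to)))
  list(nodes = data.frame(id = ids,
                          species = rep_len(species, length(ids)),
                          stringsAsFactors = FALSE),
       edges = edges)
}

triangle <- function(a, b, c, w = 1) {
  data.frame(from = c(a, a, b), to = c(b, c, c), weight = w)
}

test_that("translation selection keeps the longest span above the floor", {
  tx <- data.frame(id = c("g1", "g2", "g3"), species = "A",
                   seq = c(strrep("ATG", 200), strrep("ATG", 100),
                           strrep("ATG", 100)))
  hits <- data.frame(query = c("g1", "g1", "g2", "g3"),
                     subject = c("P1", "P1", "P2", "P3"),
                     pct_identity = 99, aln_length = 100, mismatches = 0,
                     gap_opens = 0,
                     q_start = c(1, 1, 1, 1), q_end = c(150, 450, 180, 300),
                     s_start = 1, s_end = 100,
                     evalue = c(1e-40, 1e-40, 1e-40, 1e-3),
                     bitscore = 100, frame = 1)
  out <- prepare_translations(tx, hits, min_nt_len = 200, evalue_max = 1e-5)
  expect_equal(out$id, "g1")            # g2 span 180 < 200; g3 hit too weak
  expect_equal(out$nt_span, 450L)
  expect_equal(nchar(out$protein), 150L)
})

test_that("MCL separates disconnected components and merges complete graphs", {
  g2 <- mk_graph(rbind(triangle("a1", "a2", "a3"),
                       triangle("b1", "b2", "b3")))
  fam2 <- mcl_cluster(g2, inflation = 1.6)
  expect_equal(length(unique(fam2$family)), 2L)
  expect_equal(length(unique(fam2$family[grepl("^a", fam2$id)])), 1L)

  k4 <- mk_graph(data.frame(from = c("x1", "x1", "x1", "x2", "x2", "x3"),
                            to = c("x2", "x3", "x4", "x3", "x4", "x4"),
                            weight = 1))
  expect_equal(length(unique(mcl_cluster(k4, 1.6)$family)), 1L)
})

test_that("MCL splits weakly bridged clusters and matches the reference iteration", {
  edges <- rbind(triangle("a1", "a2", "a3"),
                 triangle("b1", "b2", "b3"),
                 data.frame(from = "a1", to = "b1", weight = 0.1))
  g <- mk_graph(edges)
  fam <- mcl_cluster(g, inflation = 1.6)
  expect_equal(length(unique(fam$family)), 2L)
  ora <- oracle_mcl(g$nodes$id, edges, inflation = 1.6)
  # same partition (labels may differ): compare co-membership
  co <- function(f) outer(f, f, "==")
  expect_equal(co(fam$family[match(names(ora), fam$id)]), unname(co(ora)))
})

test_that("MCL is invariant to node order and uniform weight scaling", {
  edges <- rbind(triangle("a1", "a2", "a3"),
                 triangle("b1", "b2", "b3"),
                 data.frame(from = "a2", to = "b3", weight = 0.2))
  g1 <- mk_graph(edges)
  g2 <- mk_graph(edges[rev(seq_len(nrow(edges))), ],
                 ids = rev(sort(unique(c(edges$from, edges$to)))))
  f1 <- mcl_cluster(g1, 1.6); f2 <- mcl_cluster(g2, 1.6)
  expect_equal(f1$family, f2$family[match(f1$id, f2$id)])
  edges3 <- edges; edges3$weight <- edges3$weight * 37
  f3 <- mcl_cluster(mk_graph(edges3), 1.6)
  expect_equal(f1$family, f3$family[match(f1$id, f3$id)])
})

test_that("family Venn categories partition the families", {
  fams <- data.frame(id = c("A_1", "B_1", "C_1", "A_2", "A_3", "B_3"),
                     species = c("A", "B", "C", "A", "A", "B"),
                     family = c(1, 1, 1, 2, 3, 3))
  v <- classify_families(fams)
  expect_equal(sum(v$counts$n_families), 3L)
  expect_true(v$family_table$is_core[v$family_table$family == 1])
  expect_equal(v$counts$composition[v$counts$core], "A+B+C")
  expect_equal(v$family_table$composition[v$family_table$family == 2], "A")
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  # population 10, 5 carriers, 4 core draws, all 4 carry the term
  ann <- data.frame(gene = sprintf("g%02d", 1:10),
                    term = rep(c("T1", "T0"), each = 5))
  core <- c("g01", "g02", "g03", "g04")
  out <- hypergeom_enrichment(core, sprintf("g%02d", 1:10), ann, alpha = 1.1)
  p_t1 <- out$p[out$term == "T1"]
  expect_equal(p_t1, 5 / 210, tolerance = 1e-12)      # C(5,4)C(5,0)/C(10,4)
  expect_equal(p_t1, oracle_hyper_upper(4, 5, 10, 4), tolerance = 1e-12)
  # zero observed overlap -> p = 1 under the upper tail
  expect_equal(out$p[out$term == "T0"], 1.0)

  # p weakly decreases as overlap k grows at fixed margins
  ps <- vapply(0:4, function(k) oracle_hyper_upper(k, 5, 10, 4), numeric(1))
  expect_true(all(diff(ps) <= 0))
  # every gene annotated with a single term: no enrichment possible
  ann1 <- data.frame(gene = sprintf("g%02d", 1:10), term = "T1")
  out1 <- hypergeom_enrichment(core, sprintf("g%02d", 1:10), ann1, alpha = 1.1)
  expect_equal(out1$p, 1.0)
})

test_that("similarity_graph collapses directed hits to max-weight edges", {
  hits <- data.frame(query = c("a", "b", "a"), subject = c("b", "a", "a"),
                     bitscore = c(50, 80, 99))
  nodes <- data.frame(id = c("a", "b"), species = c("A", "B"))
  g <- similarity_graph(hits, nodes)
  expect_equal(nrow(g$edges), 1L)       # self-hit dropped, directions merged
  expect_equal(g$edges$weight, 80)
})
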