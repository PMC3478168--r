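test_that("codon degeneracy follows the enumeration rule", {
  expect_equal(classify_degeneracy("GGA", "GGA", 3), "4d")   # glycine family
  expect_equal(classify_degeneracy("ATG", "ATG", 3), "nd")   # Met is unique
  expect_equal(classify_degeneracy("CTA", "CTA", 1), "other") # CTA->TTA is Leu->Leu
  # both codons must agree; stops and Ns fall through to "other"
  expect_equal(classify_degeneracy("GGA", "ATG", 3), "other")
  expect_equal(classify_degeneracy("TAA", "TAA", 3), "other")
  expect_equal(classify_degeneracy("GGN", "GGA", 3), "other")
  # vectorized
  expect_equal(classify_degeneracy(c("GGA", "ATG"), c("GGA", "ATG"), c(3, 3)),
               c("4d", "nd"))
})

test_that("CpG columns are flagged by the union rule over full sequences", {
  # CG in A at positions 3-4 flags both columns
  expect_equal(classify_cpg("TACGT", "TATGT", 1:5, 1:5),
               c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(classify_cpg("TATAT", "TATAT", 1:5, 1:5), rep(FALSE, 5))
  # CG in B only is still flagged (symmetry)
  expect_equal(classify_cpg("TATGT", "TACGT", 1:5, 1:5),
               classify_cpg("TACGT", "TATGT", 1:5, 1:5))
  # context outside the aligned window counts
  expect_true(classify_cpg("ACGT", "AAAT", 2, 2))
})

aligned_cols <- function(n, region = "cds") {
  data.frame(i_a = seq_len(n), i_b = seq_len(n),
             phase = if (region == "cds") rep_len(0:2, n) else NA_integer_)
}

test_that("substitution counting tallies ts/tv and excludes N columns", {
  s <- strrep("GAT", 100)
  t <- count_substitutions(list(cds = aligned_cols(300)), s, s)
  all_row <- t[t$class == "all", ]
  expect_equal(all_row$substitutions, 0)
  expect_equal(all_row$compared, 300)

  s2 <- sub("GAT", "GGT", s)          # one A->G transition
  t2 <- count_substitutions(list(cds = aligned_cols(300)), s, s2)
  all2 <- t2[t2$class == "all", ]
  expect_equal(all2$substitutions, 1)
  expect_equal(all2$ts, 1)
  expect_equal(all2$tv, 0)

  # hand-built 12-column toy: 2 transitions + 1 transversion
  a <- "GATGATGATGAT"
  b <- "GACGATAATGAA"                 # T->C (ts), G->A (ts), T->A (tv)
  t3 <- count_substitutions(list(cds = aligned_cols(12)), a, b)
  all3 <- t3[t3$class == "all", ]
  expect_equal(all3$ts, 2)
  expect_equal(all3$tv, 1)
  expect_equal(all3$ts / all3$tv, 2.0)

  # N columns drop out of every tally
  t4 <- count_substitutions(list(cds = aligned_cols(12)), a,
                            sub("GAC", "GNC", b))
  expect_equal(t4[t4$class == "all", "compared"], 11)
})

test_that("class partitions are conserved and symmetric under species swap", {
  set.seed(42)
  n <- 60L
  mk <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                         collapse = "")
  for (rep in 1:5) {
    a <- mk(); b <- mk()
    t1 <- count_substitutions(list(cds = aligned_cols(n)), a, b)
    get <- function(t, cl, col) t[t$class == cl, col]
    for (col in c("substitutions", "compared", "ts", "tv")) {
      expect_equal(get(t1, "cpg", col) + get(t1, "non_cpg", col),
                   get(t1, "all", col))
      expect_equal(get(t1, "nd_noncpg", col) + get(t1, "nd_cpg", col),
                   get(t1, "nd_all", col))
    }
    expect_equal(t1$ts + t1$tv, t1$substitutions)
    t2 <- count_substitutions(list(cds = aligned_cols(n)), b, a)
    expect_equal(t1[, c("substitutions", "compared", "ts", "tv")],
                 t2[, c("substitutions", "compared", "ts", "tv")])
  }
})

test_that("pooled divergence, SE and homology match hand computation", {
  mk_tally <- function(subs, comp) {
    data.frame(region = "cds", class = "all", substitutions = subs,
               compared = comp, ts = subs, tv = 0,
               cpg_compared = 0, gc_compared = 0)
  }
  s <- summarize_divergence(list(mk_tally(1, 100), mk_tally(3, 100)))
  expect_equal(s$divergence_pct, 2.00)
  expect_equal(s$se_pct, 1.00)          # sd(c(1,3))/sqrt(2) = 1
  expect_equal(s$loci, 2L)

  s1 <- summarize_divergence(list(mk_tally(1, 100)))
  expect_true(is.na(s1$se_pct))

  h <- pair_homology(list(mk_tally(0, 100), mk_tally(0, 200)))
  expect_equal(h$stats$mean_homology_pct, 100)
  expect_equal(h$stats$min_homology_pct, 100)
  expect_equal(h$stats$mean_aligned_bp, 150)
})

test_that("category identity means respect the membership floor", {
  hom <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
                    homology_pct = c(96, 98, 99, 99, 99, 99))
  cats <- data.frame(gene = c("g1", "g2", "g1", "g3", "g4", "g5", "g6"),
                     category = c("K1", "K1", "K2", "K2", "K2", "K2", "K2"))
  out <- group_identity_by_category(hom, cats, min_members = 5)
  expect_equal(out$category, "K2")      # K1 has 2 members, suppressed
  expect_equal(out$mean_identity_pct, mean(c(96, 99, 99, 99, 99)))
  out2 <- group_identity_by_category(hom, cats, min_members = 2)
  expect_equal(out2$category[1], "K1")  # most divergent first
  expect_equal(out2$mean_identity_pct[1], 97.00)
})

test_that("derived ratios and mean aligned length recompute from totals", {
  s <- data.frame(region = c("cds", "cds", "cds", "cds"),
                  class = c("non_cpg", "cpg", "nd_all", "fourd_all"),
                  divergence_pct = c(1.25, 7.5, 0.5, 5.5))
  r <- divergence_ratios(s)
  expect_equal(r$cpg_ratio_cds, 6)
  expect_equal(r$ratio_4d_nd, 11)
  expect_equal(mean_aligned_length(1434.4, 2966), 483.6, tolerance = 1e-4)
})
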