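hit <- function(q, s, bitscore, evalue = 1e-50, frame = 0L,
                q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L) {
  data.frame(query = q, subject = s, pct_identity = 99, aln_length = 100L,
             mismatches = 1L, gap_opens = 0L, q_start = q_start,
             q_end = q_end, s_start = s_start, s_end = s_end,
             evalue = evalue, bitscore = bitscore, frame = frame,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits require mutual unique bests and length", {
  len <- c(a1 = 300L, a2 = 300L, b1 = 300L, b2 = 150L)
  ab <- rbind(hit("a1", "b1", 500), hit("a1", "b2", 300),
              hit("a2", "b1", 450))
  ba <- rbind(hit("b1", "a1", 500), hit("b1", "a2", 450),
              hit("b2", "a1", 300))
  pairs <- reciprocal_best_hits(ab, ba, len, len)
  expect_equal(pairs, data.frame(gene_a = "a1", gene_b = "b1"))

  # b1's best flips to a2 while a2's best is b2: no pair survives
  ab2 <- rbind(hit("a1", "b1", 500), hit("a2", "b1", 450),
               hit("a2", "b2", 600))
  ba2 <- rbind(hit("b1", "a2", 600), hit("b1", "a1", 500),
               hit("b2", "a1", 300))
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2, len, len)), 0L)

  # tie for best drops the query
  ab3 <- rbind(hit("a1", "b1", 500), hit("a1", "b2", 500))
  ba3 <- hit("b1", "a1", 500)
  expect_equal(nrow(reciprocal_best_hits(ab3, ba3, len, len)), 0L)

  # min length gate uses sequence length
  len2 <- c(a1 = 180L, b1 = 300L)
  expect_equal(nrow(reciprocal_best_hits(hit("a1", "b1", 500),
                                         hit("b1", "a1", 500), len2, len2)), 0L)
})

test_that("reciprocal best hits are symmetric in their arguments", {
  set.seed(5)
  len <- stats::setNames(rep(300L, 12),
                         c(paste0("a", 1:6), paste0("b", 1:6)))
  ab <- do.call(rbind, lapply(1:6, function(i)
    hit(paste0("a", i), paste0("b", sample(6, 1)), sample(100:500, 1))))
  ba <- do.call(rbind, lapply(1:6, function(i)
    hit(paste0("b", i), paste0("a", sample(6, 1)), sample(100:500, 1))))
  p1 <- reciprocal_best_hits(ab, ba, len, len)
  p2 <- reciprocal_best_hits(ba, ab, len, len)
  swapped <- data.frame(gene_a = p2$gene_b, gene_b = p2$gene_a)
  expect_equal(p1[order(p1$gene_a), ],
               swapped[order(swapped$gene_a), ],
               ignore_attr = TRUE)
})

test_that("shared-reference filtering applies the unambiguity rule", {
  cand <- data.frame(gene_a = c("a1", "a2", "a3"),
                     gene_b = c("b1", "b2", "b3"))
  pa <- rbind(hit("a1", "P1", 400, 1e-40), hit("a2", "P2", 400, 1e-40),
              hit("a3", "P3", 400, 1e-40), hit("a3", "P4", 400, 1e-40))
  pb <- rbind(hit("b1", "P1", 380, 1e-38), hit("b2", "P9", 380, 1e-38),
              hit("b3", "P3", 380, 1e-38))
  out <- filter_same_reference(cand, pa, pb)
  # a2/b2 map to different proteins; a3 is ambiguous (tied bitscore)
  expect_equal(out$gene_a, "a1")
  expect_equal(out$ref_protein, "P1")

  # E-value gate
  pa_weak <- hit("a1", "P1", 400, 1e-3)
  expect_equal(nrow(filter_same_reference(cand[1, ], pa_weak, pb)), 0L)
})

test_that("delineation projects the reference start and stop onto the transcript", {
  # "AA" + ATG GCT GCT ... TGA + "CC"; reference protein of 11 residues
  cds <- paste0("ATG", strrep("GCT", 10), "TGA")
  tx <- paste0("AA", cds, "CC")
  h <- hit("t1", "P1", 300, 1e-40, frame = 3L,
           q_start = 3L, q_end = 35L, s_start = 1L, s_end = 11L)
  part <- delineate_regions(tx, h, ref_protein_len = 11L)
  expect_equal(part$cds_start, 3L)
  expect_equal(part$cds_end, 38L)       # stop codon included
  expect_equal(part$utr5, c(1L, 2L))
  expect_equal(part$utr3, c(39L, 40L))
  expect_false(part$start_missing)
  expect_false(part$stop_missing)

  # reference stop projecting 6 bp before the true in-frame TGA is
  # still accepted (within the 30 bp window)
  h_short <- hit("t1", "P1", 300, 1e-40, frame = 3L,
                 q_start = 3L, q_end = 29L, s_start = 1L, s_end = 9L)
  part2 <- delineate_regions(tx, h_short, ref_protein_len = 9L)
  expect_false(part2$stop_missing)
  expect_equal(part2$cds_end, 38L)

  # no ATG anywhere: partial flag, CDS clipped to the aligned region
  tx3 <- paste0("AA", "CTG", strrep("GCT", 10), "TGA", "CC")
  part3 <- delineate_regions(tx3, h, ref_protein_len = 11L)
  expect_true(part3$start_missing)
  expect_equal(part3$cds_start, 3L)
})

test_that("negative-frame hits reorient the transcript before delineation", {
  cds <- paste0("ATG", strrep("GCT", 10), "TGA")
  tx <- paste0("AA", cds, "CC")
  rc <- orthodiv:::revcomp(tx)
  len <- nchar(tx)
  # coordinates of the hit on the reverse-complemented input
  h <- hit("t1", "P1", 300, 1e-40, frame = -1L,
           q_start = len - 35L + 1L, q_end = len - 3L + 1L,
           s_start = 1L, s_end = 11L)
  part <- delineate_regions(rc, h, ref_protein_len = 11L)
  expect_true(part$reoriented)
  expect_equal(part$seq, tx)
  expect_equal(part$cds_start, 3L)
})

test_that("CDS filters drop short and internally terminated sequences", {
  good <- list(seq = paste0("ATG", strrep("GCT", 60), "TGA"),
               cds_start = 1L, cds_end = 186L)
  short <- list(seq = paste0("ATG", strrep("GCT", 47), "TGA"),
                cds_start = 1L, cds_end = 147L)
  expect_true(filter_regions(good, good))
  r <- filter_regions(good, short)
  expect_false(r); expect_equal(attr(r, "reason"), "cds_too_short")

  internal <- list(seq = paste0("ATG", strrep("GCT", 20), "TAA",
                                strrep("GCT", 40), "TGA"),
                   cds_start = 1L, cds_end = 189L)
  r2 <- filter_regions(good, internal)
  expect_false(r2); expect_equal(attr(r2, "reason"), "internal_stop")
})

test_that("region alignment is codon-aware with gap columns excluded", {
  cds_a <- strrep("GATCCA", 50)          # 300 bp, no stop at end
  part <- function(seq) list(seq = seq, cds_start = 1L, cds_end = nchar(seq),
                             utr5 = NULL, utr3 = NULL)
  aln <- align_pair_regions(part(cds_a), part(cds_a))
  expect_equal(nrow(aln$cds), 300L)
  expect_equal(aln$cds$i_a, aln$cds$i_b)

  # one inserted codon in one member: its columns are absent
  cds_b <- paste0(substr(cds_a, 1, 150), "AAA", substr(cds_a, 151, 300))
  aln2 <- align_pair_regions(part(cds_a), part(cds_b))
  expect_equal(nrow(aln2$cds), 300L)
  expect_false(any(aln2$cds$i_b %in% 151:153))
})

test_that("short or weak UTR alignments are discarded, CDS retained", {
  cds <- paste0("ATG", strrep("GCT", 40), "TGA")
  mk <- function(utr5) list(seq = paste0(utr5, cds),
                            cds_start = nchar(utr5) + 1L,
                            cds_end = nchar(utr5) + nchar(cds),
                            utr5 = c(1L, nchar(utr5)), utr3 = NULL)
  # identical 12-bp UTRs: 100% identity but below the 30-bp block floor
  aln <- align_pair_regions(mk("ACGTACGTACGT"), mk("ACGTACGTACGT"))
  expect_null(aln$utr5)
  expect_gt(nrow(aln$cds), 0)
  # identical 40-bp UTRs pass
  u <- strrep("ACGTAGGTAC", 4)
  aln2 <- align_pair_regions(mk(u), mk(u))
  expect_equal(nrow(aln2$utr5), 40L)

  # unrelated random UTRs almost never yield an accepted block
  set.seed(9)
  hits <- 0
  for (i in 1:10) {
    u1 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    u2 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    a <- align_pair_regions(mk(u1), mk(u2))
    if (!is.null(a$utr5)) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("zero-divergence synthetic pairs recover exact CDS boundaries", {
  p <- evol_params(n_genes = 8, t_A = 0, t_B = 0, t_C = 0,
                   paralog_frac = 0, seed = 42)
  ds <- simulate_dataset(p, withr::local_tempdir())
  orth <- orthology_stage(parse_blast_tab(ds$files$tx_A_vs_B),
                          parse_blast_tab(ds$files$tx_B_vs_A),
                          parse_blast_tab(ds$files$prot_A),
                          parse_blast_tab(ds$files$prot_B),
                          read_fasta(ds$files$fasta_A, "A"),
                          read_fasta(ds$files$fasta_B, "B"))
  expect_equal(nrow(orth$pairs), 8L)
  reg <- ds$truth$regions
  for (key in names(orth$partitions)) {
    g <- gene_of_id(strsplit(key, "|", fixed = TRUE)[[1]][1])
    row <- reg[reg$gene == g, ]
    expect_equal(orth$partitions[[key]]$a$cds_start, row$cds_start)
    expect_equal(orth$partitions[[key]]$a$cds_end, row$cds_end)
  }
})
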