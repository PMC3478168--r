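## Within-species SNP detection on orthologous CDS regions from read
## pileups, with synonymous/nonsynonymous classification.

#' Pile up read bases over CDS intervals
#'
#' Walks each alignment's CIGAR (M advances both, I consumes read only,
#' D consumes reference only; other operations are not expected in the
#' minimal dialect) and accumulates per-base counts restricted to the
#' CDS interval of each target.
#'
#' @param alignments data.frame from [parse_sam_min()].
#' @param cds_intervals data.frame with columns `gene`, `cds_start`,
#'   `cds_end` (1-based inclusive, transcript coordinates).
#' @return data.frame: `gene`, `cds_pos` (1-based within the CDS),
#'   `A`, `C`, `G`, `T`, `depth`.  Alignments to targets without a CDS
#'   interval are skipped (count reported as attribute `n_skipped`).
#' @export
pileup_cds <- function(alignments, cds_intervals) {
  iv <- stats::setNames(split(cds_intervals[, c("cds_start", "cds_end")],
                              seq_len(nrow(cds_intervals))),
                        cds_intervals$gene)
  counts <- list()   # gene -> 4 x cds_len matrix
  for (g in cds_intervals$gene) {
    len <- cds_intervals$cds_end[cds_intervals$gene == g] -
           cds_intervals$cds_start[cds_intervals$gene == g] + 1L
    counts[[g]] <- matrix(0L, nrow = 4, ncol = len,
                          dimnames = list(BASES, NULL))
  }
  n_skipped <- 0L
  known <- alignments$target_id %in% names(counts)
  n_skipped <- sum(!known)
  alignments <- alignments[known, , drop = FALSE]

  ## fast path: plain "<n>M" alignments, accumulated per gene with
  ## tabulate over (base, position) indices
  simple <- grepl("^\\d+M$", alignments$cigar)
  if (any(simple)) {
    simp <- alignments[simple, , drop = FALSE]
    rl <- nchar(simp$seq)
    for (g in unique(simp$target_id)) {
      sel <- simp$target_id == g
      cs <- iv[[g]]$cds_start; ce <- iv[[g]]$cds_end
      len <- ce - cs + 1L
      starts <- simp$pos[sel]
      b <- unlist(strsplit(simp$seq[sel], "", fixed = TRUE), use.names = FALSE)
      rp <- unlist(lapply(which(sel), function(i)
        simp$pos[i]:(simp$pos[i] + nchar(simp$seq[i]) - 1L)), use.names = FALSE)
      in_cds <- rp >= cs & rp <= ce & b %in% BASES
      if (!any(in_cds)) next
      idx <- (match(b[in_cds], BASES) - 1L) * len + (rp[in_cds] - cs + 1L)
      acc <- tabulate(idx, nbins = 4L * len)
      counts[[g]] <- counts[[g]] + matrix(acc, nrow = 4, ncol = len, byrow = TRUE)
    }
    alignments <- alignments[!simple, , drop = FALSE]
  }
  for (i in seq_len(nrow(alignments))) {
    g <- alignments$target_id[i]
    cs <- iv[[g]]$cds_start; ce <- iv[[g]]$cds_end
    ref_pos <- alignments$pos[i]; read_pos <- 1L
    bases <- strsplit(alignments$seq[i], "", fixed = TRUE)[[1]]
    cig <- parse_cigar(alignments$cigar[i])
    for (k in seq_along(cig$op)) {
      op <- cig$op[k]; ln <- cig$len[k]
      if (op %in% c("M", "=", "X")) {
        rp <- ref_pos:(ref_pos + ln - 1L)
        qp <- read_pos:(read_pos + ln - 1L)
        in_cds <- rp >= cs & rp <= ce
        if (any(in_cds)) {
          b <- bases[qp[in_cds]]
          pos <- rp[in_cds] - cs + 1L
          ok <- b %in% BASES
          if (any(ok)) {
            idx <- cbind(match(b[ok], BASES), pos[ok])
            for (r in seq_len(nrow(idx))) {
              counts[[g]][idx[r, 1], idx[r, 2]] <- counts[[g]][idx[r, 1], idx[r, 2]] + 1L
            }
          }
        }
        ref_pos <- ref_pos + ln; read_pos <- read_pos + ln
      } else if (op == "I") {
        read_pos <- read_pos + ln
      } else if (op %in% c("D", "N")) {
        ref_pos <- ref_pos + ln
      } else if (op == "S") {
        read_pos <- read_pos + ln
      }
    }
  }
  rows <- lapply(names(counts), function(g) {
    m <- counts[[g]]
    depth <- colSums(m)
    keep <- which(depth > 0)
    if (!length(keep)) return(NULL)
    data.frame(gene = g, cds_pos = keep,
               A = m["A", keep], C = m["C", keep],
               G = m["G", keep], T = m["T", keep],
               depth = depth[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(0), cds_pos = integer(0),
                                      A = integer(0), C = integer(0),
                                      G = integer(0), T = integer(0),
                                      depth = integer(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Call SNPs from pileup columns
#'
#' A site is called when depth >= `min_depth`, and the most frequent
#' base differing from the transcript consensus has count >=
#' `min_alt_count` and frequency >= `min_alt_freq`.  The depth gate is
#' the primary filter; the alternate-allele support gates suppress
#' singleton noise.
#'
#' @param columns data.frame from [pileup_cds()].
#' @param cds_seqs named character vector gene -> CDS sequence (the
#'   transcript consensus; supplies the reference allele).
#' @param min_depth minimum depth (default 10).
#' @param min_alt_count minimum alternate-allele count (default 3).
#' @param min_alt_freq minimum alternate-allele frequency (default 0.2).
#' @return data.frame of calls: `gene`, `cds_pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `alt_freq`.
#' @export
call_snps <- function(columns, cds_seqs, min_depth = 10L,
                      min_alt_count = 3L, min_alt_freq = 0.2) {
  if (nrow(columns) == 0) {
    return(data.frame(gene = character(0), cds_pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      alt_freq = numeric(0)))
  }
  ref <- substring(cds_seqs[columns$gene], columns$cds_pos, columns$cds_pos)
  cnt <- as.matrix(columns[, BASES])
  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), match(ref, BASES))] <- -1L
  alt_idx <- max.col(alt_cnt, ties.method = "first")
  alt <- BASES[alt_idx]
  alt_count <- cnt[cbind(seq_len(nrow(cnt)), alt_idx)]
  keep <- columns$depth >= min_depth & alt_count >= min_alt_count &
          alt_count / columns$depth >= min_alt_freq & !is.na(ref) & nzchar(ref)
  out <- data.frame(gene = columns$gene[keep], cds_pos = columns$cds_pos[keep],
                    ref = ref[keep], alt = alt[keep],
                    depth = columns$depth[keep],
                    alt_count = alt_count[keep],
                    alt_freq = alt_count[keep] / columns$depth[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify the coding effect of a SNP
#'
#' Substitutes the alternate base into its codon: synonymous when the
#' amino acid is unchanged, nonsynonymous otherwise (a change to a stop
#' codon is nonsynonymous).  Codons containing `N` give
#' `"undetermined"`.
#'
#' @param cds_seq CDS sequence of the gene.
#' @param cds_pos 1-based position within the CDS.
#' @param alt alternate base.
#' @return list: `effect` (`"synonymous"`, `"nonsynonymous"` or
#'   `"undetermined"`), `ref_aa`, `alt_aa`, `codon_index` (1-based),
#'   `phase` (0..2).
#' @export
classify_snp_effect <- function(cds_seq, cds_pos, alt) {
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  phase <- (cds_pos - 1L) %% 3L
  start <- 3L * (codon_index - 1L) + 1L
  ref_codon <- substr(cds_seq, start, start + 2L)
  if (nchar(ref_codon) < 3L) {
    return(list(effect = "undetermined", ref_aa = NA, alt_aa = NA,
                codon_index = codon_index, phase = phase))
  }
  alt_codon <- mutate_codon(ref_codon, phase + 1L, alt)
  aa <- codon_aa()
  if (!(ref_codon %in% names(aa)) || !(alt_codon %in% names(aa))) {
    return(list(effect = "undetermined", ref_aa = NA, alt_aa = NA,
                codon_index = codon_index, phase = phase))
  }
  ref_aa <- unname(aa[ref_codon]); alt_aa <- unname(aa[alt_codon])
  list(effect = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
       ref_aa = ref_aa, alt_aa = alt_aa,
       codon_index = codon_index, phase = phase)
}

#' SNP stage: pileup, calling and effect classification
#'
#' @param sam data.frame from [parse_sam_min()].
#' @param cds_intervals data.frame `gene`, `cds_start`, `cds_end`.
#' @param seqs named vector of full transcript sequences.
#' @param config settings list (see [default_config()]).
#' @return data.frame of annotated SNP calls.
#' @export
snp_stage <- function(sam, cds_intervals, seqs, config = default_config()) {
  cols <- pileup_cds(sam, cds_intervals)
  cds_seqs <- stats::setNames(
    substring(seqs[cds_intervals$gene], cds_intervals$cds_start,
              cds_intervals$cds_end),
    cds_intervals$gene)
  calls <- call_snps(cols, cds_seqs, min_depth = config$snp_min_depth,
                     min_alt_count = config$snp_min_alt_count,
                     min_alt_freq = config$snp_min_alt_freq)
  if (nrow(calls) == 0) {
    calls$effect <- character(0); calls$ref_aa <- character(0)
    calls$alt_aa <- character(0)
    return(calls)
  }
  eff <- lapply(seq_len(nrow(calls)), function(i) {
    classify_snp_effect(cds_seqs[[calls$gene[i]]], calls$cds_pos[i], calls$alt[i])
  })
  calls$effect <- vapply(eff, `[[`, "", "effect")
  calls$ref_aa <- vapply(eff, function(e) as.character(e$ref_aa %||% NA), "")
  calls$alt_aa <- vapply(eff, function(e) as.character(e$alt_aa %||% NA), "")
  calls
}
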