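## Reciprocal-best-hit orthology, paralog filtering by shared reference
## protein, and rule-based CDS/UTR delineation from translated-search
## hits.

## Best subject per query by bitscore; queries whose top bitscore is
## tied between subjects are dropped (conservative "unambiguous" rule).
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(query = character(0), subject = character(0),
                      evalue = numeric(0), bitscore = numeric(0)))
  }
  rows <- lapply(split(hits, hits$query), function(g) {
    top <- max(g$bitscore)
    best <- g[g$bitscore == top, , drop = FALSE]
    if (length(unique(best$subject)) > 1) return(NULL)  # ambiguous
    best[1, c("query", "subject", "evalue", "bitscore"), drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(query = character(0), subject = character(0),
                                      evalue = numeric(0), bitscore = numeric(0))
  rownames(out) <- NULL
  out
}

#' Reciprocal-best-hit candidate ortholog pairs
#'
#' A pair `(a, b)` is kept when `b` is `a`'s unique best hit by bitscore
#' in the A-vs-B table, `a` is `b`'s unique best hit in the B-vs-A
#' table, and both sequences are at least `min_len` bp.  Ties for best
#' hit drop the query.
#'
#' @param hits_ab,hits_ba hit tables from [parse_blast_tab()].
#' @param len_a,len_b named integer vectors of sequence lengths.
#' @param min_len minimum sequence length in bp (default 200).
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, len_a, len_b, min_len = 200L) {
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  ba_map <- stats::setNames(best_ba$subject, best_ba$query)
  mutual <- ba_map[best_ab$subject] == best_ab$query
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(gene_a = best_ab$query[mutual],
                    gene_b = best_ab$subject[mutual],
                    stringsAsFactors = FALSE)
  keep <- len_a[out$gene_a] >= min_len & len_b[out$gene_b] >= min_len
  keep[is.na(keep)] <- FALSE
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep candidate pairs whose members map unambiguously to the same
#' reference protein
#'
#' Each member's best protein hit (by bitscore; a bitscore tie between
#' different proteins makes the member ambiguous and drops the pair)
#' must have E-value below `evalue_max` and both best hits must name
#' the same protein.  This is the paralog filter: a duplicated gene and
#' its source map to the same protein, but the duplicate loses the
#' reciprocal-best-hit race, and genes whose members map to different
#' proteins are discarded here.
#'
#' @param candidates data.frame from [reciprocal_best_hits()].
#' @param prot_hits_a,prot_hits_b translated-search hit tables.
#' @param evalue_max maximum E-value (default 1e-5).
#' @return data.frame of ortholog pairs: `gene_a`, `gene_b`,
#'   `ref_protein`, `evalue_a`, `evalue_b`.
#' @export
filter_same_reference <- function(candidates, prot_hits_a, prot_hits_b,
                                  evalue_max = 1e-5) {
  best_a <- best_hit_per_query(prot_hits_a)
  best_b <- best_hit_per_query(prot_hits_b)
  ia <- match(candidates$gene_a, best_a$query)
  ib <- match(candidates$gene_b, best_b$query)
  ok <- !is.na(ia) & !is.na(ib)
  ok[ok] <- best_a$evalue[ia[ok]] < evalue_max &
            best_b$evalue[ib[ok]] < evalue_max &
            best_a$subject[ia[ok]] == best_b$subject[ib[ok]]
  out <- data.frame(gene_a = candidates$gene_a[ok],
                    gene_b = candidates$gene_b[ok],
                    ref_protein = best_a$subject[ia[ok]],
                    evalue_a = best_a$evalue[ia[ok]],
                    evalue_b = best_b$evalue[ib[ok]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## The best protein hit row (full 13 columns) per query, NULL if absent
## or ambiguous.
best_protein_hit <- function(prot_hits, gene) {
  g <- prot_hits[prot_hits$query == gene, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  top <- max(g$bitscore)
  best <- g[g$bitscore == top, , drop = FALSE]
  if (length(unique(best$subject)) > 1) return(NULL)
  best[1, , drop = FALSE]
}

#' Delineate CDS and UTR regions of a transcript from its reference
#' protein hit
#'
#' The first reference residue is projected onto the transcript through
#' the hit coordinates; the start codon is the in-frame ATG nearest
#' that projection (searching upstream within the transcript first,
#' then downstream within the aligned region) and the stop codon is the
#' in-frame TAA/TAG/TGA nearest the projected reference stop, within
#' +/- `stop_window` bp (inclusive).  A missing start or stop sets a
#' partial flag and clips the CDS to the aligned region.  Negative-frame
#' hits reverse-complement the transcript first; all coordinates refer
#' to the re-oriented sequence.
#'
#' @param seq transcript sequence.
#' @param prot_hit one hit row (13 columns, frame set).
#' @param ref_protein_len reference protein length in residues.
#' @param stop_window bp window around the projected stop (default 30).
#' @return list with `seq` (possibly reverse-complemented), `cds_start`,
#'   `cds_end` (1-based inclusive, stop codon included), `utr5`, `utr3`
#'   (each `c(start, end)` or `NULL`), `start_missing`, `stop_missing`,
#'   `reoriented`; or `NULL` with attribute `reason` when no CDS can be
#'   placed.
#' @export
delineate_regions <- function(seq, prot_hit, ref_protein_len, stop_window = 30L) {
  len <- nchar(seq)
  q_start <- prot_hit$q_start; q_end <- prot_hit$q_end
  reoriented <- FALSE
  if (prot_hit$frame < 0) {
    seq <- revcomp(seq)
    qs <- len - q_end + 1L; qe <- len - q_start + 1L
    q_start <- qs; q_end <- qe
    reoriented <- TRUE
  }
  if (q_end - q_start + 1L < 3L) {
    out <- NULL; attr(out, "reason") <- "no_alignment"; return(out)
  }
  proj_start <- q_start - 3L * (prot_hit$s_start - 1L)
  frame_mod <- ((proj_start - 1L) %% 3L)
  inframe <- function(p) ((p - 1L) %% 3L) == frame_mod
  codon_at <- function(p) substr(seq, p, p + 2L)

  ## start codon: upstream-first within the transcript, then downstream
  ## within the aligned region
  cds_start <- NA_integer_
  p <- min(proj_start, q_start + ((proj_start - q_start) %% 3L))
  up <- seq(from = if (proj_start >= 1L) proj_start else proj_start + 3L * ceiling((1L - proj_start) / 3L),
            to = 1L, by = -3L)
  up <- up[up >= 1L & up + 2L <= len]
  for (pp in up) if (codon_at(pp) == "ATG") { cds_start <- pp; break }
  if (is.na(cds_start)) {
    down <- seq(from = proj_start + 3L, to = q_end - 2L, by = 3L)
    down <- down[down >= 1L & down + 2L <= len]
    for (pp in down) if (codon_at(pp) == "ATG") { cds_start <- pp; break }
  }
  start_missing <- is.na(cds_start)
  if (start_missing) {
    cds_start <- max(1L, q_start)
    cds_start <- cds_start + ((proj_start - cds_start) %% 3L)  # keep frame
  }

  ## stop codon: nearest in-frame stop within the window around the
  ## projected reference stop (ties resolved upstream)
  proj_stop <- q_start + 3L * (ref_protein_len - prot_hit$s_start + 1L)
  cand <- seq(from = proj_stop - 3L * (stop_window %/% 3L),
              to = proj_stop + 3L * (stop_window %/% 3L), by = 3L)
  cand <- cand[abs(cand - proj_stop) <= stop_window]
  cand <- cand[inframe(cand) & cand >= cds_start + 3L & cand + 2L <= len]
  stops <- cand[vapply(cand, function(p) codon_at(p) %in% STOP_CODONS, logical(1))]
  stop_missing <- length(stops) == 0L
  if (!stop_missing) {
    stop_pos <- stops[order(abs(stops - proj_stop), stops)][1]
    cds_end <- stop_pos + 2L
  } else {
    lim <- min(q_end, len)
    cds_end <- cds_start + 3L * ((lim - cds_start + 1L) %/% 3L) - 1L
  }
  if (is.na(cds_end) || cds_end < cds_start + 2L) {
    out <- NULL; attr(out, "reason") <- "no_cds"; return(out)
  }
  list(seq = seq, cds_start = cds_start, cds_end = cds_end,
       utr5 = if (cds_start > 1L) c(1L, cds_start - 1L) else NULL,
       utr3 = if (cds_end < len) c(cds_end + 1L, len) else NULL,
       start_missing = start_missing, stop_missing = stop_missing,
       reoriented = reoriented)
}

#' Apply CDS quality filters to a delineated pair
#'
#' Drops the pair when either member's CDS is shorter than `cds_min` bp
#' or contains an internal in-frame stop codon (the terminal stop is
#' allowed).
#'
#' @param part_a,part_b partitions from [delineate_regions()].
#' @param cds_min minimum CDS length in bp (default 150).
#' @return `TRUE` to keep, otherwise `FALSE` with attribute `reason`.
#' @export
filter_regions <- function(part_a, part_b, cds_min = 150L) {
  for (part in list(part_a, part_b)) {
    cds_len <- part$cds_end - part$cds_start + 1L
    if (cds_len < cds_min) {
      out <- FALSE; attr(out, "reason") <- "cds_too_short"; return(out)
    }
    cds <- substr(part$seq, part$cds_start, part$cds_end)
    stops <- inframe_stops(cds)
    internal <- stops[stops < nchar(cds) - 2L]
    if (length(internal)) {
      out <- FALSE; attr(out, "reason") <- "internal_stop"; return(out)
    }
  }
  TRUE
}

## Walk two gapped aligned strings and return the 1-based coordinates of
## gapless columns in the original (sub)sequences.
gapless_columns <- function(aln_a, aln_b, off_a = 0L, off_b = 0L) {
  ca <- strsplit(aln_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln_b, "", fixed = TRUE)[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  data.frame(i_a = off_a + ia[keep], i_b = off_b + ib[keep])
}

#' Align the delineated regions of an ortholog pair
#'
#' The CDS is aligned codon-aware: both CDS (terminal stop codon
#' removed) are translated and globally aligned with a BLOSUM62 matrix
#' (gap open 11, extend 1), and the protein alignment is back-mapped to
#' nucleotides; columns where either member is gapped are excluded.
#' UTRs are aligned by local nucleotide alignment (match +2, mismatch
#' -3, gap open 5, extend 2) keeping the single best block, which must
#' span at least `utr_min_block` aligned columns at
#' `utr_min_ident` percent identity or the UTR pair is discarded.
#'
#' @param part_a,part_b partitions from [delineate_regions()].
#' @param utr_min_block,utr_min_ident UTR acceptance surrogate
#'   (defaults 30 bp, 70 percent).
#' @return named list of aligned-column data.frames (`i_a`, `i_b`,
#'   `phase`) in full-transcript coordinates; regions that fail or are
#'   absent are omitted.
#' @export
align_pair_regions <- function(part_a, part_b,
                               utr_min_block = 30L, utr_min_ident = 70) {
  out <- list()
  ## --- CDS, codon-aware ---
  cds_a <- substr(part_a$seq, part_a$cds_start, part_a$cds_end)
  cds_b <- substr(part_b$seq, part_b$cds_start, part_b$cds_end)
  trim <- function(s) if (substr(s, nchar(s) - 2, nchar(s)) %in% STOP_CODONS)
    substr(s, 1, nchar(s) - 3) else s
  cds_a <- trim(cds_a); cds_b <- trim(cds_b)
  if (nchar(cds_a) >= 3 && nchar(cds_b) >= 3) {
    pa <- translate_cds(cds_a); pb <- translate_cds(cds_b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pa), Biostrings::AAString(pb),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "global")
    cols <- gapless_columns(as.character(Biostrings::alignedPattern(aln)),
                            as.character(Biostrings::alignedSubject(aln)))
    if (nrow(cols)) {
      nt_a <- part_a$cds_start - 1L + rep(3L * (cols$i_a - 1L), each = 3L) + 1:3
      nt_b <- part_b$cds_start - 1L + rep(3L * (cols$i_b - 1L), each = 3L) + 1:3
      out$cds <- data.frame(i_a = nt_a, i_b = nt_b,
                            phase = rep_len(0:2, length(nt_a)))
    }
  }
  ## --- UTRs, local nucleotide ---
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  for (rg in c("utr5", "utr3")) {
    iv_a <- part_a[[rg]]; iv_b <- part_b[[rg]]
    if (is.null(iv_a) || is.null(iv_b)) next
    sa <- substr(part_a$seq, iv_a[1], iv_a[2])
    sb <- substr(part_b$seq, iv_b[1], iv_b[2])
    if (nchar(sa) < 2 || nchar(sb) < 2) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(sa), Biostrings::DNAString(sb),
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
      type = "local")
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    if (!nzchar(pat)) next
    cols <- gapless_columns(pat, sub,
                            off_a = Biostrings::start(Biostrings::pattern(aln)) - 1L,
                            off_b = Biostrings::start(Biostrings::subject(aln)) - 1L)
    if (nrow(cols) < utr_min_block) next
    ident <- 100 * mean(substring(sa, cols$i_a, cols$i_a) ==
                        substring(sb, cols$i_b, cols$i_b))
    if (ident < utr_min_ident) next
    out[[rg]] <- data.frame(i_a = iv_a[1] - 1L + cols$i_a,
                            i_b = iv_b[1] - 1L + cols$i_b,
                            phase = NA_integer_)
  }
  out
}

#' Run the full orthology stage for one species pair
#'
#' Chains [reciprocal_best_hits()], [filter_same_reference()],
#' [delineate_regions()], [filter_regions()] and
#' [align_pair_regions()].
#'
#' @param hits_ab,hits_ba transcript-vs-transcript hit tables.
#' @param prot_a,prot_b transcript-vs-reference-protein hit tables.
#' @param seqs_a,seqs_b transcript tables from [read_fasta()].
#' @param ref_protein_len named vector of reference protein lengths; if
#'   `NULL`, taken as `s_end` of each best hit (full-length hits).
#' @param config settings list (see [default_config()]).
#' @return list with `pairs` (accepted pairs), `partitions` and
#'   `aligned` (both named by `gene_a|gene_b`), and `dropped` reasons.
#' @export
orthology_stage <- function(hits_ab, hits_ba, prot_a, prot_b,
                            seqs_a, seqs_b, ref_protein_len = NULL,
                            config = default_config()) {
  len_a <- stats::setNames(nchar(seqs_a$seq), seqs_a$id)
  len_b <- stats::setNames(nchar(seqs_b$seq), seqs_b$id)
  cand <- reciprocal_best_hits(hits_ab, hits_ba, len_a, len_b,
                               min_len = config$min_len)
  pairs <- filter_same_reference(cand, prot_a, prot_b,
                                 evalue_max = config$prot_evalue)
  seq_a <- stats::setNames(seqs_a$seq, seqs_a$id)
  seq_b <- stats::setNames(seqs_b$seq, seqs_b$id)
  partitions <- list(); aligned <- list(); dropped <- character(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    key <- paste(ga, gb, sep = "|")
    ha <- best_protein_hit(prot_a, ga); hb <- best_protein_hit(prot_b, gb)
    rl_a <- if (!is.null(ref_protein_len)) ref_protein_len[[ha$subject]] else ha$s_end
    rl_b <- if (!is.null(ref_protein_len)) ref_protein_len[[hb$subject]] else hb$s_end
    pa <- delineate_regions(seq_a[[ga]], ha, rl_a, stop_window = config$stop_window)
    pb <- delineate_regions(seq_b[[gb]], hb, rl_b, stop_window = config$stop_window)
    if (is.null(pa) || is.null(pb)) {
      dropped[key] <- attr(pa, "reason") %||% attr(pb, "reason"); next
    }
    ok <- filter_regions(pa, pb, cds_min = config$cds_min)
    if (!isTRUE(ok)) { dropped[key] <- attr(ok, "reason"); next }
    aln <- align_pair_regions(pa, pb, utr_min_block = config$utr_min_block,
                              utr_min_ident = config$utr_min_ident)
    if (is.null(aln$cds) || nrow(aln$cds) == 0) { dropped[key] <- "empty_cds_alignment"; next }
    partitions[[key]] <- list(a = pa, b = pb)
    aligned[[key]] <- aln
    keep[i] <- TRUE
  }
  list(pairs = pairs[keep, , drop = FALSE], partitions = partitions,
       aligned = aligned, dropped = dropped)
}
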