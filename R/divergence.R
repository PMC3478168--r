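## Site-class divergence engine: classifies aligned columns by region
## (5'UTR / CDS / 3'UTR), degeneracy (nondegenerate / fourfold
## degenerate) and CpG context, and tallies substitutions, transitions
## and transversions per class across ortholog pairs.

#' Classify codon-position degeneracy for a pair of codons
#'
#' A position is nondegenerate (`"nd"`) when every possible base change
#' alters the encoded amino acid, and fourfold degenerate (`"4d"`) when
#' none does; a change to a stop codon counts as amino-acid-changing.
#' The label is assigned only when *both* codons give the same label;
#' disagreeing, ambiguous (containing `N`) or stop codons yield
#' `"other"`.
#'
#' @param codon_a,codon_b character vectors of 3-letter codons.
#' @param position codon position, 1 to 3 (recycled).
#' @return character vector of labels among `"nd"`, `"4d"`, `"other"`.
#' @export
classify_degeneracy <- function(codon_a, codon_b, position) {
  n <- max(length(codon_a), length(codon_b), length(position))
  codon_a <- rep_len(toupper(codon_a), n)
  codon_b <- rep_len(toupper(codon_b), n)
  position <- rep_len(as.integer(position), n)
  stopifnot(all(position %in% 1:3))
  deg <- degeneracy_table()
  lab <- rep("other", n)
  known <- codon_a %in% rownames(deg) & codon_b %in% rownames(deg)
  ok <- known & !is_stop_codon(ifelse(known, codon_a, "TAA")) &
        !is_stop_codon(ifelse(known, codon_b, "TAA"))
  idx <- which(ok)
  if (length(idx)) {
    ra <- match(codon_a[idx], rownames(deg))
    rb <- match(codon_b[idx], rownames(deg))
    la <- deg[cbind(ra, position[idx])]
    lb <- deg[cbind(rb, position[idx])]
    agree <- la == lb & la %in% c("nd", "4d")
    lab[idx[agree]] <- la[agree]
  }
  lab
}

## Per-base CpG flags for one full sequence: a base is flagged when it
## is the C or the G of a 5'-CG-3' dinucleotide.
cpg_flags <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  cg_left <- b == "C" & c(b[-1], "") == "G"        # C of a CG
  cg_right <- b == "G" & c("", b[-n]) == "C"       # G of a CG
  cg_left | cg_right
}

#' Flag CpG columns of an aligned pair
#'
#' A column is CpG when its base participates in a CG dinucleotide in
#' *either* full sequence (the CG partner may lie outside the aligned
#' region).  The union rule makes the flag symmetric under swapping the
#' two species.
#'
#' @param seq_a,seq_b full nucleotide sequences.
#' @param cols_a,cols_b 1-based positions of the aligned columns in each
#'   sequence.
#' @return logical vector, one flag per column.
#' @export
classify_cpg <- function(seq_a, seq_b, cols_a, cols_b) {
  stopifnot(length(cols_a) == length(cols_b))
  cpg_flags(seq_a)[cols_a] | cpg_flags(seq_b)[cols_b]
}

DIVERGENCE_CLASSES <- list(
  utr5 = c("all", "non_cpg", "cpg"),
  cds  = c("all", "non_cpg", "cpg", "nd_all", "nd_noncpg", "nd_cpg",
           "fourd_all", "fourd_noncpg", "fourd_cpg"),
  utr3 = c("all", "non_cpg", "cpg"))

## Build the per-column classification table for one aligned region of
## one ortholog pair.  `aligned` is a data.frame with columns i_a, i_b
## (1-based positions) and, for CDS, phase (0/1/2).
region_columns <- function(region, aligned, seq_a, seq_b) {
  if (nrow(aligned) == 0) return(NULL)
  base_a <- substring(seq_a, aligned$i_a, aligned$i_a)
  base_b <- substring(seq_b, aligned$i_b, aligned$i_b)
  keep <- base_a != "N" & base_b != "N"
  df <- data.frame(region = region,
                   i_a = aligned$i_a[keep], i_b = aligned$i_b[keep],
                   base_a = base_a[keep], base_b = base_b[keep],
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(NULL)
  df$cpg <- classify_cpg(seq_a, seq_b, df$i_a, df$i_b)
  if (region == "cds") {
    phase <- aligned$phase[keep]
    cod_a <- substring(seq_a, df$i_a - phase, df$i_a - phase + 2)
    cod_b <- substring(seq_b, df$i_b - phase, df$i_b - phase + 2)
    df$deg <- classify_degeneracy(cod_a, cod_b, phase + 1L)
  } else {
    df$deg <- "na"
  }
  df
}

## Tally one pair's columns into per-(region, class) counts.
tally_pair_columns <- function(cols) {
  if (is.null(cols) || nrow(cols) == 0) return(NULL)
  mism <- cols$base_a != cols$base_b
  ts <- mism & is_transition(cols$base_a, cols$base_b)
  gc_a <- cols$base_a %in% c("G", "C")
  cell <- function(sel, region, class) {
    data.frame(region = region, class = class,
               substitutions = sum(mism[sel]), compared = sum(sel),
               ts = sum(ts[sel]), tv = sum(mism[sel]) - sum(ts[sel]),
               cpg_compared = sum(cols$cpg[sel]),
               gc_compared = sum(gc_a[sel]), stringsAsFactors = FALSE)
  }
  out <- list()
  for (region in unique(cols$region)) {
    r <- cols$region == region
    out[[length(out) + 1L]] <- cell(r, region, "all")
    out[[length(out) + 1L]] <- cell(r & !cols$cpg, region, "non_cpg")
    out[[length(out) + 1L]] <- cell(r & cols$cpg, region, "cpg")
    if (region == "cds") {
      for (d in c("nd", "4d")) {
        pre <- if (d == "nd") "nd" else "fourd"
        s <- r & cols$deg == d
        out[[length(out) + 1L]] <- cell(s, region, paste0(pre, "_all"))
        out[[length(out) + 1L]] <- cell(s & !cols$cpg, region, paste0(pre, "_noncpg"))
        out[[length(out) + 1L]] <- cell(s & cols$cpg, region, paste0(pre, "_cpg"))
      }
    }
  }
  do.call(rbind, out)
}

#' Count substitutions per site class for one aligned pair
#'
#' @param aligned_regions named list of aligned-column data.frames (names
#'   among `utr5`, `cds`, `utr3`; each with columns `i_a`, `i_b` and, for
#'   `cds`, `phase`), as produced by [align_pair_regions()].
#' @param seq_a,seq_b the two full transcript sequences.
#' @return data.frame of per-(region, class) counts: substitutions,
#'   compared sites, transitions (`ts`), transversions (`tv`), CpG and
#'   G/C compared-site counts.  Columns containing `N` are excluded
#'   entirely.
#' @export
count_substitutions <- function(aligned_regions, seq_a, seq_b) {
  cols <- do.call(rbind, lapply(names(aligned_regions), function(rg) {
    region_columns(rg, aligned_regions[[rg]], seq_a, seq_b)
  }))
  tally_pair_columns(cols)
}

#' Pool per-pair tallies into a divergence summary
#'
#' Pooled divergence per cell is total substitutions over total compared
#' sites.  The reported standard error is the across-locus SE (standard
#' deviation of per-locus divergences over the square root of the locus
#' count); the binomial SE of the pooled proportion is emitted alongside
#' as `se_binom_pct`.
#'
#' @param pair_tallies list of per-pair tally data.frames from
#'   [count_substitutions()].
#' @return data.frame with one row per (region, class): locus count,
#'   substitutions, compared bp, divergence and SE in percent, ts/tv and
#'   the percent of compared sites that are CpG or G/C.
#' @export
summarize_divergence <- function(pair_tallies) {
  pair_tallies <- Filter(Negate(is.null), pair_tallies)
  if (!length(pair_tallies)) stopf("no pairs to summarize")
  all_rows <- do.call(rbind, lapply(seq_along(pair_tallies), function(i) {
    t <- pair_tallies[[i]]; t$pair_index <- i; t
  }))
  key <- interaction(all_rows$region, all_rows$class, drop = TRUE)
  out <- lapply(split(all_rows, key), function(g) {
    g <- g[g$compared > 0, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    subs <- sum(g$substitutions); comp <- sum(g$compared)
    p <- subs / comp
    per_locus <- 100 * g$substitutions / g$compared
    data.frame(region = g$region[1], class = g$class[1],
               loci = nrow(g), substitutions = subs, compared_bp = comp,
               divergence_pct = 100 * p,
               se_pct = if (nrow(g) > 1) stats::sd(per_locus) / sqrt(nrow(g)) else NA_real_,
               se_binom_pct = 100 * sqrt(p * (1 - p) / comp),
               ts = sum(g$ts), tv = sum(g$tv),
               ts_tv = if (sum(g$tv) > 0) sum(g$ts) / sum(g$tv) else NA_real_,
               pct_cpg = 100 * sum(g$cpg_compared) / comp,
               pct_gc = 100 * sum(g$gc_compared) / comp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  region_order <- c(utr5 = 1, cds = 2, utr3 = 3)
  class_order <- stats::setNames(seq_along(DIVERGENCE_CLASSES$cds),
                                 DIVERGENCE_CLASSES$cds)
  out <- out[order(region_order[out$region], class_order[out$class]), ]
  rownames(out) <- NULL
  out
}

#' Per-pair homology table and its summary statistics
#'
#' Homology of a pair is 100 minus its CDS divergence in percent; the
#' summary reports pair count, total and mean aligned length, the
#' longest alignment, and mean/min/max homology.  Two candidate
#' dispersion statistics are emitted (standard deviation of the
#' per-pair divergence as a proportion and as a percent).
#'
#' @param pair_tallies list of per-pair tally data.frames.
#' @param pair_ids optional character vector of pair identifiers.
#' @return list with elements `pairs` (per-pair table) and `stats`.
#' @export
pair_homology <- function(pair_tallies, pair_ids = NULL) {
  pair_tallies <- Filter(Negate(is.null), pair_tallies)
  rows <- lapply(seq_along(pair_tallies), function(i) {
    t <- pair_tallies[[i]]
    cds <- t[t$region == "cds" & t$class == "all", , drop = FALSE]
    if (nrow(cds) == 0 || cds$compared == 0) return(NULL)
    data.frame(pair = if (is.null(pair_ids)) sprintf("pair%04d", i) else pair_ids[i],
               aligned_bp = cds$compared,
               substitutions = cds$substitutions,
               homology_pct = 100 * (1 - cds$substitutions / cds$compared),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) stopf("no pairs with compared CDS")
  div_prop <- 1 - pairs$homology_pct / 100
  list(pairs = pairs,
       stats = data.frame(
         n_pairs = nrow(pairs),
         total_aligned_kb = sum(pairs$aligned_bp) / 1000,
         mean_aligned_bp = mean(pairs$aligned_bp),
         longest_aligned_bp = max(pairs$aligned_bp),
         mean_homology_pct = mean(pairs$homology_pct),
         min_homology_pct = min(pairs$homology_pct),
         max_homology_pct = max(pairs$homology_pct),
         sd_divergence_prop = stats::sd(div_prop),
         sd_divergence_pct = stats::sd(100 * div_prop)))
}

#' Mean pair identity by annotation category
#'
#' @param homology data.frame with columns `gene` and `homology_pct`
#'   (one row per ortholog pair, keyed by one member's gene id).
#' @param categories data.frame with columns `gene` and `category`; a
#'   gene may carry several categories and then contributes to each.
#' @param min_members categories with fewer pairs are suppressed
#'   (default 5).
#' @return data.frame of category, n_pairs and mean identity, sorted
#'   most-divergent first.
#' @export
group_identity_by_category <- function(homology, categories, min_members = 5L) {
  merged <- merge(homology, categories, by = "gene")
  if (nrow(merged) == 0) {
    return(data.frame(category = character(0), n_pairs = integer(0),
                      mean_identity_pct = numeric(0)))
  }
  agg <- stats::aggregate(homology_pct ~ category, data = merged,
                          FUN = function(x) c(n = length(x), m = mean(x)))
  out <- data.frame(category = agg$category,
                    n_pairs = as.integer(agg$homology_pct[, "n"]),
                    mean_identity_pct = agg$homology_pct[, "m"],
                    stringsAsFactors = FALSE)
  out <- out[out$n_pairs >= min_members, , drop = FALSE]
  out <- out[order(out$mean_identity_pct, out$category), ]
  rownames(out) <- NULL
  out
}

#' Derived ratio columns of a divergence summary
#'
#' Recomputes, from a per-class summary table, the headline ratios of a
#' site-class divergence analysis: the CpG over non-CpG divergence
#' ratio per region and the fourfold-degenerate over nondegenerate
#' ratio for CDS.
#'
#' @param summary data.frame with at least columns `region`, `class`,
#'   `divergence_pct` (as from [summarize_divergence()], or a published
#'   summary read from TSV).
#' @return named list of ratios: `cpg_ratio_<region>` for each region
#'   present and `ratio_4d_nd` when the nd/4d rows exist.
#' @export
divergence_ratios <- function(summary) {
  get1 <- function(region, class) {
    v <- summary$divergence_pct[summary$region == region & summary$class == class]
    if (length(v) == 1) v else NA_real_
  }
  out <- list()
  for (region in unique(summary$region)) {
    cpg <- get1(region, "cpg"); ncpg <- get1(region, "non_cpg")
    if (!is.na(cpg) && !is.na(ncpg) && ncpg > 0) {
      out[[paste0("cpg_ratio_", region)]] <- cpg / ncpg
    }
  }
  nd <- get1("cds", "nd_all"); fd <- get1("cds", "fourd_all")
  if (!is.na(nd) && !is.na(fd) && nd > 0) out$ratio_4d_nd <- fd / nd
  out
}

#' Mean aligned length from totals
#'
#' @param total_kb total aligned length in kilobases.
#' @param loci number of ortholog pairs.
#' @return mean aligned length in bp.
#' @export
mean_aligned_length <- function(total_kb, loci) 1000 * total_kb / loci
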