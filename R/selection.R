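## Nei-Gojobori (1986) counting of synonymous and nonsynonymous sites
## and differences, Jukes-Cantor correction to Ka and Ks, and a Fisher
## exact test of the difference/site contingency table.

## Average synonymous/nonsynonymous step counts over all minimal
## mutational paths between two codons.  Paths passing through a stop
## codon are excluded; mutations *to* a stop codon in the final state
## never arise here because stop codons are skipped upstream.
## Returns c(sd, nd) or NULL when every path is blocked.
ng86_path_average <- function(cod_a, cod_b) {
  aa <- codon_aa()
  diffs <- which(strsplit(cod_a, "")[[1]] != strsplit(cod_b, "")[[1]])
  k <- length(diffs)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(diffs)
           else if (k == 2) list(diffs, rev(diffs))
           else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) diffs[o])
  }
  tot_sd <- 0; tot_nd <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- cod_a; sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- mutate_codon(cur, pos, substr(cod_b, pos, pos))
      if (aa[nxt] == "*") { blocked <- TRUE; break }
      if (aa[nxt] == aa[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) { tot_sd <- tot_sd + sd; tot_nd <- tot_nd + nd; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(NULL)
  c(sd = tot_sd / n_ok, nd = tot_nd / n_ok)
}

#' NG86 site and difference counts for a codon-aligned pair
#'
#' Synonymous-site fractions are computed per codon position by
#' enumerating the three alternative bases (changes to stop codons count
#' as nonsynonymous) and averaged between the two sequences; observed
#' differences are resolved by averaging over all minimal substitution
#' paths between differing codons, excluding paths through stop codons.
#' Codon pairs containing `N`, a gap character or a stop codon — or
#' whose every path is blocked by a stop — are skipped.
#'
#' @param seq_a,seq_b equal-length in-frame nucleotide strings.
#' @return list with `S`, `N` (synonymous / nonsynonymous sites), `Sd`,
#'   `Nd` (differences), `codons_used` and `codons_skipped`.
#' @export
ng86_site_counts <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stopf("sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stopf("length %d not divisible by 3", nchar(seq_a))
  cods_a <- split_codons(toupper(seq_a))
  cods_b <- split_codons(toupper(seq_b))
  sf <- syn_fraction_table()
  S <- 0; Sd <- 0; Nd <- 0; used <- 0L; skipped <- 0L
  for (i in seq_along(cods_a)) {
    ca <- cods_a[i]; cb <- cods_b[i]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb) ||
        is_stop_codon(ca) || is_stop_codon(cb)) { skipped <- skipped + 1L; next }
    d <- ng86_path_average(ca, cb)
    if (is.null(d)) { skipped <- skipped + 1L; next }
    S <- S + sum(sf[ca, ] + sf[cb, ]) / 2
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    used <- used + 1L
  }
  list(S = S, N = 3 * used - S, Sd = Sd, Nd = Nd,
       codons_used = used, codons_skipped = skipped)
}

#' Ka/Ks estimate from NG86 counts
#'
#' Applies the Jukes-Cantor correction `K = -3/4 * log(1 - 4/3 * p)` to
#' the synonymous and nonsynonymous difference proportions.  The
#' correction diverges when `4/3 * p >= 1`; the affected rate, and any
#' ratio involving it, is reported as `NA` with a flag.
#'
#' @param counts list from [ng86_site_counts()].
#' @param pair optional pair identifier carried into the result.
#' @return one-row data.frame: pair, S, N, Sd, Nd, ps, pn, Ks, Ka,
#'   ka_ks, flag (`"ok"`, `"ks_zero"`, `"saturated"` or `"no_sites"`).
#' @export
kaks_estimate <- function(counts, pair = NA_character_) {
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ps <- if (counts$S > 0) counts$Sd / counts$S else NA_real_
  pn <- if (counts$N > 0) counts$Nd / counts$N else NA_real_
  Ks <- jc(ps); Ka <- jc(pn)
  flag <- "ok"
  if (is.na(ps) || is.na(pn)) flag <- "no_sites"
  else if (is.na(Ks) || is.na(Ka)) flag <- "saturated"
  else if (Ks == 0) flag <- "ks_zero"
  ratio <- if (flag == "ok") Ka / Ks else NA_real_
  data.frame(pair = pair, S = counts$S, N = counts$N,
             Sd = counts$Sd, Nd = counts$Nd, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, ka_ks = ratio, flag = flag,
             stringsAsFactors = FALSE)
}

#' Fisher exact test of synonymous vs nonsynonymous differences
#'
#' Tests the 2x2 table `[[Sd, S - Sd], [Nd, N - Nd]]` (differences vs
#' remaining sites, by site type).  Site and difference counts are real
#' valued under NG86 and are rounded to the nearest integer first.  The
#' two-sided p-value sums all hypergeometric table probabilities not
#' exceeding the observed table's probability (with a `1 + 1e-7`
#' relative tie guard).
#'
#' @param S,Sd,N,Nd counts as in [ng86_site_counts()].
#' @return two-sided p-value.
#' @export
fisher_exact_kaks <- function(S, Sd, N, Nd) {
  S <- round(S); Sd <- round(Sd); N <- round(N); Nd <- round(Nd)
  if (min(S - Sd, N - Nd, S, N, Sd, Nd) < 0) {
    stopf("negative cell in Fisher table after rounding")
  }
  k <- Sd + Nd                      # total differences drawn
  if (k == 0 || S + N == 0) return(1)
  x <- max(0, k - N):min(k, S)      # feasible synonymous-difference counts
  probs <- stats::dhyper(x, S, N, k)
  p_obs <- stats::dhyper(Sd, S, N, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Ka/Ks over a set of ortholog CDS pairs
#'
#' @param cds_pairs named list; each element a list with `a` and `b`
#'   equal-length in-frame CDS strings.
#' @return data.frame, one row per pair, with NG86 counts, rates, ratio
#'   and Fisher p (`fisher_p`).
#' @export
kaks_table <- function(cds_pairs) {
  rows <- lapply(names(cds_pairs), function(id) {
    p <- cds_pairs[[id]]
    counts <- ng86_site_counts(p$a, p$b)
    row <- kaks_estimate(counts, pair = id)
    row$fisher_p <- if (row$flag %in% c("ok", "ks_zero"))
      fisher_exact_kaks(counts$S, counts$Sd, counts$N, counts$Nd) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
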