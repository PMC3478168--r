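# Direct Monte-Carlo oracle for per-class divergence expectations: an
# independent re-implementation of the stated mutation process and of
# the downstream site classification, run on the ancestral gene set and
# measured on the true regions.  Used to check the pipeline's pooled
# estimates without sharing its code paths.

# memoized 64 x 64 x 3 pair-degeneracy table built from the enumeration
# oracle
oracle_pair_deg_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    codons <- names(oracle_codon_table())
    t3 <- array("other", dim = c(64, 64, 3), dimnames = list(codons, codons, NULL))
    single <- array("", dim = c(64, 3))
    for (i in seq_along(codons)) for (p in 1:3)
      single[i, p] <- oracle_degeneracy1(codons[i], p)
    for (p in 1:3) {
      for (i in seq_along(codons)) for (j in seq_along(codons)) {
        la <- single[i, p]; lb <- single[j, p]
        if (la == lb && la %in% c("nd", "4d") &&
            oracle_translate1(codons[i]) != "*" &&
            oracle_translate1(codons[j]) != "*") {
          t3[i, j, p] <- la
        }
      }
    }
    tab <<- t3
    tab
  }
})

oracle_cpg_flags <- function(chars) {
  n <- length(chars)
  is_c <- chars == "C"; is_g <- chars == "G"
  (is_c & c(is_g[-1], FALSE)) | (is_g & c(FALSE, is_c[-n]))
}

# Independent single-branch evolution under the stated model.
oracle_evolve_chars <- function(anc, cds_start, cds_end, t, params) {
  n <- length(anc)
  cpg <- oracle_cpg_flags(anc)
  in_cds <- seq_len(n) >= cds_start & seq_len(n) <= cds_end
  ts_w <- ifelse(cpg, params$kappa * params$cpg_mult, params$kappa)
  p <- t * (ts_w + 2) / (params$kappa + 2)
  p[!in_cds] <- p[!in_cds] * params$utr_rate_mult
  hit <- which(stats::runif(n) < pmin(1, p))
  out <- anc
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  aa_tab <- oracle_codon_table()
  for (i in hit) {
    ref <- anc[i]
    alt <- if (stats::runif(1) < ts_w[i] / (ts_w[i] + 2)) partner[[ref]] else
      sample(setdiff(ORACLE_BASES, c(ref, partner[[ref]])), 1)
    if (in_cds[i]) {
      ph <- (i - cds_start) %% 3L
      cs <- i - ph
      cod <- paste0(anc[cs], anc[cs + 1], anc[cs + 2])
      mut <- cod
      substr(mut, ph + 1, ph + 1) <- alt
      if (aa_tab[cod] == "*") { if (aa_tab[mut] != "*") next }
      else if (aa_tab[mut] == "*") next
      else if (aa_tab[mut] != aa_tab[cod]) {
        f <- if (oracle_degeneracy1(cod, ph + 1) == "nd") params$f_nd else params$f_ns
        if (stats::runif(1) >= f) next
      }
    }
    out[i] <- alt
  }
  out
}

# Tally one evolved pair into per-(region, class) counts using
# oracle-side classification (union CpG on the evolved pair, both-codon
# agreement for degeneracy, terminal stop codon excluded from CDS).
oracle_tally_pair <- function(sa, sb, cds_start, cds_end) {
  n <- length(sa)
  cpg <- oracle_cpg_flags(sa) | oracle_cpg_flags(sb)
  region <- rep("utr3", n)
  region[seq_len(n) < cds_start] <- "utr5"
  region[seq_len(n) >= cds_start & seq_len(n) <= cds_end - 3L] <- "cds"
  region[seq_len(n) > cds_end - 3L & seq_len(n) <= cds_end] <- "stop"
  mism <- sa != sb
  ts <- mism & ((sa == "A" & sb == "G") | (sa == "G" & sb == "A") |
                (sa == "C" & sb == "T") | (sa == "T" & sb == "C"))
  deg <- rep("na", n)
  idx <- which(region == "cds")
  if (length(idx)) {
    ph <- (idx - cds_start) %% 3L
    cs <- idx - ph
    codons <- names(oracle_codon_table())
    cod_a <- paste0(sa[cs], sa[cs + 1], sa[cs + 2])
    cod_b <- paste0(sb[cs], sb[cs + 1], sb[cs + 2])
    tab <- oracle_pair_deg_table()
    deg[idx] <- tab[cbind(match(cod_a, codons), match(cod_b, codons), ph + 1)]
  }
  cell <- function(sel, region_name, class) {
    data.frame(region = region_name, class = class,
               substitutions = sum(mism[sel]), compared = sum(sel),
               ts = sum(ts[sel]), tv = sum(mism[sel] & !ts[sel]))
  }
  out <- list()
  for (rg in c("utr5", "cds", "utr3")) {
    r <- region == rg
    out[[length(out) + 1]] <- cell(r, rg, "all")
    out[[length(out) + 1]] <- cell(r & !cpg, rg, "non_cpg")
    out[[length(out) + 1]] <- cell(r & cpg, rg, "cpg")
    if (rg == "cds") {
      for (d in c("nd", "4d")) {
        pre <- if (d == "nd") "nd" else "fourd"
        s <- r & deg == d
        out[[length(out) + 1]] <- cell(s, rg, paste0(pre, "_all"))
        out[[length(out) + 1]] <- cell(s & !cpg, rg, paste0(pre, "_noncpg"))
        out[[length(out) + 1]] <- cell(s & cpg, rg, paste0(pre, "_cpg"))
      }
    }
  }
  do.call(rbind, out)
}

# Pooled Monte-Carlo expectation over n_reps independent evolutions of
# every ancestor along the two branches, with binomial MC standard
# errors.
oracle_divergence_mc <- function(ancestors, t1, t2, params, n_reps = 2,
                                 seed = 20260922) {
  set.seed(seed %% 2147483647)
  acc <- NULL
  for (rep in seq_len(n_reps)) {
    for (i in seq_len(nrow(ancestors$genes))) {
      g <- ancestors$genes[i, ]
      anc <- strsplit(g$seq, "", fixed = TRUE)[[1]]
      sa <- oracle_evolve_chars(anc, g$cds_start, g$cds_end, t1, params)
      sb <- oracle_evolve_chars(anc, g$cds_start, g$cds_end, t2, params)
      t <- oracle_tally_pair(sa, sb, g$cds_start, g$cds_end)
      if (is.null(acc)) {
        acc <- t
      } else {
        acc$substitutions <- acc$substitutions + t$substitutions
        acc$compared <- acc$compared + t$compared
        acc$ts <- acc$ts + t$ts
        acc$tv <- acc$tv + t$tv
      }
    }
  }
  acc$divergence_pct <- 100 * acc$substitutions / acc$compared
  p <- acc$substitutions / acc$compared
  acc$se_pct <- 100 * sqrt(p * (1 - p) / acc$compared)
  acc
}
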