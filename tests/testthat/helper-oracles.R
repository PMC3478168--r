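# Independent oracles used across the suite.  Each re-derives the
# quantity from first principles by enumeration or direct simulation,
# deliberately avoiding the package's own code paths.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      names(gc) <- chartr("U", "T", names(gc))
      tab <<- gc
    }
    tab
  }
})

oracle_translate1 <- function(codon) unname(oracle_codon_table()[codon])

# Degeneracy of one codon position by explicit enumeration of the three
# alternative bases.
oracle_degeneracy1 <- function(codon, pos) {
  aa0 <- oracle_translate1(codon)
  if (aa0 == "*") return("other")
  changes <- 0L
  for (b in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (oracle_translate1(mut) != aa0) changes <- changes + 1L
  }
  if (changes == 3L) "nd" else if (changes == 0L) "4d" else "other"
}

# Pair rule: label only when both codons agree.
oracle_degeneracy_pair <- function(ca, cb, pos) {
  la <- oracle_degeneracy1(ca, pos)
  lb <- oracle_degeneracy1(cb, pos)
  if (la == lb && la %in% c("nd", "4d")) la else "other"
}

# NG86 synonymous-site fraction of one codon (sum over positions).
oracle_syn_sites <- function(codon) {
  aa0 <- oracle_translate1(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(ORACLE_BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate1(mut) == aa0) s <- s + 1 / 3
    }
  }
  s
}

# NG86 difference counts by recursive enumeration of every minimal
# path, dropping paths that pass through a stop codon.
oracle_ng86_diffs <- function(ca, cb) {
  paths <- list()
  walk <- function(cur, sd, nd) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(diffs)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (pos in diffs) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (oracle_translate1(nxt) == "*") next
      if (oracle_translate1(nxt) == oracle_translate1(cur)) {
        walk(nxt, sd + 1, nd)
      } else {
        walk(nxt, sd, nd + 1)
      }
    }
  }
  walk(ca, 0, 0)
  if (!length(paths)) return(NULL)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Hypergeometric upper tail P(X >= k) via lchoose sums.
oracle_hyper_upper <- function(k, K, pop, ndraw) {
  xs <- k:min(K, ndraw)
  xs <- xs[ndraw - xs <= pop - K]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(pop - K, ndraw - xs) - lchoose(pop, ndraw)))
}

# Two-sided Fisher p for [[a, b], [c, d]] by full enumeration over the
# fixed-margin family, summing probabilities <= observed (relative tie
# guard 1e-7).
oracle_fisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(lp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Straightforward reference implementation of the MCL iteration with
# explicit loops, independent of the package's vectorized version.
oracle_mcl <- function(nodes, edges, inflation, tol = 1e-8, max_iter = 200) {
  ids <- sort(nodes)
  n <- length(ids)
  M <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], ids); j <- match(edges$to[r], ids)
    M[i, j] <- edges$weight[r]; M[j, i] <- edges$weight[r]
  }
  for (j in seq_len(n)) {
    mx <- max(M[, j]); M[j, j] <- if (mx > 0) mx else 1
  }
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) E[i, j] <- sum(M[i, ] * M[, j])
    E <- E ^ inflation
    E[E < 1e-12] <- 0
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    if (max(abs(E - M)) < tol) { M <- E; break }
    M <- E
  }
  adj <- (M > 0) | (t(M) > 0)
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  stats::setNames(comp, ids)
}

# SAM fixture writer used by io and snp tests.
write_sam_fixture <- function(path, sq, records) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sq), unname(sq)),
             records)
  writeLines(lines, path)
}

sam_record <- function(qname, flag, rname, pos, cigar, seq) {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, cigar, seq, strrep("I", nchar(seq)))
}
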