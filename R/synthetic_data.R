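## Sequence-evolution simulator: ortholog triples descending from common
## ancestors under a per-site mutation model with CpG hypermutability,
## transition bias and purifying constraint at nondegenerate sites;
## planted paralogs; log-normal read abundances; planted heterozygous
## SNPs; and the similarity/annotation tables the pipeline consumes.
## Every output is reproducible byte-for-byte from one seed.

#' Simulation parameters
#'
#' Defaults describe a three-species transcriptome comparison in which
#' one species (A) sits on a branch about twice as long as the other
#' two: branch lengths `t_A = 0.02`, `t_B = t_C = 0.005` expected
#' substitutions per site, transition/transversion rate ratio
#' `kappa = 4`, CpG transition-rate multiplier `cpg_mult = 6` (CpG
#' hypermutability acts through cytosine deamination, so only the
#' transition channel is elevated), acceptance probability `f_nd = 0.1`
#' for amino-acid-changing mutations at nondegenerate sites and
#' `f_ns = 0.5` at other sites, UTR rate multiplier 1.2, 10 percent
#' planted paralogs, a mean of 0.2 planted heterozygous SNPs per gene
#' and 74-bp reads at 40x target mean depth.
#'
#' @param n_genes number of ancestral genes (default 500).
#' @param cds_len_range,utr5_len_range,utr3_len_range length ranges in
#'   bp (CDS lengths are rounded to multiples of 3).
#' @param t_A,t_B,t_C branch lengths in expected substitutions/site.
#' @param kappa transition/transversion rate ratio.
#' @param cpg_mult transition-rate multiplier at ancestral CpG sites.
#' @param f_nd,f_ns acceptance probabilities for amino-acid-changing
#'   mutations at nondegenerate / other CDS sites.
#' @param utr_rate_mult rate multiplier in UTRs.
#' @param paralog_frac fraction of genes duplicated in one species.
#' @param het_rate mean planted heterozygous SNPs per gene.
#' @param read_len read length in bp (default 74).
#' @param mean_depth target mean coverage; sets the read total when
#'   `total_reads` is `NULL` (default 40).
#' @param total_reads total simulated reads per species; overrides
#'   `mean_depth` when given.
#' @param spurious_rate per-query probability of a spurious similarity
#'   hit (default 0.01).
#' @param seed master seed; every stream derives from it.
#' @return validated parameter list of class `evol_params`.
#' @export
evol_params <- function(n_genes = 500L,
                        cds_len_range = c(300L, 900L),
                        utr5_len_range = c(60L, 200L),
                        utr3_len_range = c(90L, 300L),
                        t_A = 0.02, t_B = 0.005, t_C = 0.005,
                        kappa = 4, cpg_mult = 6,
                        f_nd = 0.1, f_ns = 0.5,
                        utr_rate_mult = 1.2,
                        paralog_frac = 0.1, het_rate = 0.2,
                        read_len = 74L, mean_depth = 40,
                        total_reads = NULL,
                        spurious_rate = 0.01, seed = 1L) {
  p <- as.list(environment())
  for (rg in c("cds_len_range", "utr5_len_range", "utr3_len_range")) {
    if (p[[rg]][1] > p[[rg]][2]) stopf("degenerate range for %s (min > max)", rg)
  }
  if (any(c(t_A, t_B, t_C, kappa, cpg_mult, utr_rate_mult, het_rate) < 0))
    stopf("rates must be non-negative")
  if (f_nd < 0 || f_nd > 1 || f_ns < 0 || f_ns > 1) stopf("f_nd, f_ns must be in [0,1]")
  if (read_len < 20) stopf("read_len must be >= 20")
  structure(p, class = "evol_params")
}

sample_range <- function(r, n) if (r[1] == r[2]) rep(r[1], n) else
  sample(seq(r[1], r[2]), n, replace = TRUE)

#' Simulate codon-structured ancestral genes
#'
#' Each ancestor is 5'UTR + CDS + 3'UTR; the CDS starts with ATG, ends
#' with a single stop codon and contains no internal stops.
#'
#' @param params from [evol_params()].
#' @return list with `genes` (data.frame: `gene`, `seq`, `cds_start`,
#'   `cds_end`, lengths, `ref_protein`, `prot_len`) and `params`.
#' @export
simulate_ancestors <- function(params) {
  stopifnot(inherits(params, "evol_params"))
  set.seed(od_subseed(params$seed, "ancestors"))
  n <- params$n_genes
  u5 <- sample_range(params$utr5_len_range, n)
  u3 <- sample_range(params$utr3_len_range, n)
  cds <- 3L * pmax(3L, round(sample_range(params$cds_len_range, n) / 3))
  sense <- setdiff(sense_codons(), "ATG")
  genes <- lapply(seq_len(n), function(i) {
    interior <- sample(sense, cds[i] / 3 - 2, replace = TRUE)
    cds_seq <- paste0("ATG", paste(interior, collapse = ""),
                      sample(STOP_CODONS, 1))
    utr5 <- paste(sample(BASES, u5[i], replace = TRUE), collapse = "")
    utr3 <- paste(sample(BASES, u3[i], replace = TRUE), collapse = "")
    paste0(utr5, cds_seq, utr3)
  })
  ids <- sprintf("g%04d", seq_len(n))
  df <- data.frame(gene = ids, seq = unlist(genes),
                   utr5_len = u5, cds_len = cds, utr3_len = u3,
                   cds_start = u5 + 1L, cds_end = u5 + cds,
                   ref_protein = paste0("P_", ids),
                   prot_len = cds / 3 - 1L, stringsAsFactors = FALSE)
  list(genes = df, params = params)
}

## Evolve one sequence along one branch.  Mutations are proposed per
## site at rate t times the class multipliers (CpG context and UTR/CDS
## status frozen at the ancestor), transitions favoured kappa-fold;
## amino-acid-changing proposals are accepted with probability f_nd at
## nondegenerate sites and f_ns elsewhere; proposals creating or
## destroying a stop codon are rejected.  Assumes the caller seeded the
## RNG.
evolve_seq <- function(anc_seq, cds_start, cds_end, t, params) {
  n <- nchar(anc_seq)
  if (t <= 0) return(anc_seq)
  b <- strsplit(anc_seq, "", fixed = TRUE)[[1]]
  cpg <- cpg_flags(anc_seq)
  in_cds <- seq_len(n) >= cds_start & seq_len(n) <= cds_end
  ## CpG hypermutability is transition-specific (cytosine deamination):
  ## the transition weight is kappa * cpg_mult at ancestral CpG sites and
  ## kappa elsewhere; each transversion has weight 1.  t is calibrated so
  ## a non-CpG site proposes at rate t.
  ts_w <- ifelse(cpg, params$kappa * params$cpg_mult, params$kappa)
  rate <- t * (ts_w + 2) / (params$kappa + 2)
  rate[!in_cds] <- rate[!in_cds] * params$utr_rate_mult
  proposed <- which(stats::runif(n) < pmin(1, rate))
  if (!length(proposed)) return(anc_seq)
  deg <- degeneracy_table()
  aa <- codon_aa()
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  out <- b
  for (i in proposed) {
    ref <- b[i]
    if (stats::runif(1) < ts_w[i] / (ts_w[i] + 2)) {
      alt <- ts_partner[[ref]]
    } else {
      alt <- sample(setdiff(BASES, c(ref, ts_partner[[ref]])), 1)
    }
    if (in_cds[i]) {
      off <- i - cds_start               # 0-based within CDS
      pos <- off %% 3L + 1L
      cod_start <- i - (pos - 1L)
      cod <- paste0(b[cod_start], b[cod_start + 1L], b[cod_start + 2L])
      new_cod <- mutate_codon(cod, pos, alt)
      if (aa[cod] == "*") {              # ancestral stop: stay a stop
        if (aa[new_cod] != "*") next
      } else {
        if (aa[new_cod] == "*") next     # never create a stop
        if (aa[new_cod] != aa[cod]) {
          f <- if (deg[cod, pos] == "nd") params$f_nd else params$f_ns
          if (stats::runif(1) >= f) next
        }
      }
    }
    out[i] <- alt
  }
  paste(out, collapse = "")
}

#' Evolve the ancestral genes into three species
#'
#' Species A, B and C evolve independently from each ancestor along
#' branches `t_A`, `t_B`, `t_C`; see [evol_params()] for the mutation
#' model.  Setting all branch lengths to zero returns three identical
#' copies of each ancestor.
#'
#' @param ancestors from [simulate_ancestors()].
#' @return list with `species` (named list of transcript data.frames,
#'   ids prefixed `A_`/`B_`/`C_`), `truth` (ortholog map + region
#'   table) and `params`.
#' @export
evolve_triple <- function(ancestors) {
  params <- ancestors$params
  anc <- ancestors$genes
  branch <- c(A = params$t_A, B = params$t_B, C = params$t_C)
  species <- lapply(names(branch), function(sp) {
    seqs <- vapply(seq_len(nrow(anc)), function(i) {
      set.seed(od_subseed(params$seed, paste0("evolve:", sp, ":", anc$gene[i])))
      evolve_seq(anc$seq[i], anc$cds_start[i], anc$cds_end[i],
                 branch[[sp]], params)
    }, character(1))
    data.frame(id = paste0(sp, "_", anc$gene), species = sp, seq = seqs,
               stringsAsFactors = FALSE)
  })
  names(species) <- names(branch)
  map <- data.frame(gene = anc$gene,
                    id_A = paste0("A_", anc$gene),
                    id_B = paste0("B_", anc$gene),
                    id_C = paste0("C_", anc$gene), stringsAsFactors = FALSE)
  truth <- list(regions = anc, map = map,
                paralogs = data.frame(gene = character(0), species = character(0),
                                      source_id = character(0),
                                      paralog_id = character(0)))
  list(species = species, truth = truth, params = params)
}

#' Plant paralogs by duplicating genes with extra divergence
#'
#' `paralog_frac` of the genes are duplicated in one (randomly chosen)
#' species; the duplicate evolves further from the existing copy with
#' branch length twice that species' branch, so it is always more
#' diverged from the other species' orthologs than the original copy.
#'
#' @param triple from [evolve_triple()].
#' @return the triple with augmented species sets and a filled paralog
#'   registry in `truth$paralogs`.
#' @export
plant_paralogs <- function(triple) {
  params <- triple$params
  n_par <- round(params$paralog_frac * params$n_genes)
  if (n_par == 0) return(triple)
  set.seed(od_subseed(params$seed, "paralogs"))
  anc <- triple$truth$regions
  pick <- sort(sample(anc$gene, n_par))
  sp_pick <- sample(names(triple$species), n_par, replace = TRUE)
  branch <- c(A = params$t_A, B = params$t_B, C = params$t_C)
  reg <- lapply(seq_along(pick), function(k) {
    g <- pick[k]; sp <- sp_pick[k]
    src_id <- paste0(sp, "_", g)
    src <- triple$species[[sp]]
    row <- anc[anc$gene == g, ]
    set.seed(od_subseed(params$seed, paste0("paralog:", g)))
    dup <- evolve_seq(src$seq[src$id == src_id], row$cds_start, row$cds_end,
                      2 * branch[[sp]], params)
    par_id <- paste0(src_id, "_par")
    triple$species[[sp]] <<- rbind(src, data.frame(id = par_id, species = sp,
                                                   seq = dup, stringsAsFactors = FALSE))
    data.frame(gene = g, species = sp, source_id = src_id,
               paralog_id = par_id, stringsAsFactors = FALSE)
  })
  triple$truth$paralogs <- do.call(rbind, reg)
  triple
}

## Length, cds bounds and reference info for any transcript id
## (paralogs inherit their source gene's layout).
gene_of_id <- function(id) sub("_par$", "", sub("^[ABC]_", "", id))

#' Simulate reads and planted heterozygous SNPs for one species
#'
#' Per-gene read counts follow a log-normal abundance times length
#' (drawn as one multinomial so the total is exact); reads are
#' error-free, ungapped, 74 bp by default, with uniform start
#' positions.  Heterozygous SNPs (count per gene Poisson with mean
#' `het_rate`, positions uniform in the CDS, allele frequency 0.5) are
#' planted by drawing each read from one of two haplotypes.
#'
#' @param triple from [plant_paralogs()] / [evolve_triple()].
#' @param sp species label (default `"A"`).
#' @param path output SAM file.
#' @return list with `path`, `snps` (planted-SNP registry),
#'   `abundance` (per-gene expected weight and realized read count).
#' @export
simulate_reads <- function(triple, sp = "A", path) {
  params <- triple$params
  set.seed(od_subseed(params$seed, paste0("reads:", sp)))
  tx <- triple$species[[sp]]
  tx <- tx[!grepl("_par$", tx$id), , drop = FALSE]  # reads target orthologs
  reg <- triple$truth$regions
  len <- nchar(tx$seq)
  ok <- len >= params$read_len
  if (any(!ok)) warning(sprintf("%d transcripts shorter than read_len skipped", sum(!ok)))
  tx <- tx[ok, , drop = FALSE]; len <- len[ok]

  ## plant heterozygous SNPs
  n_snp <- stats::rpois(nrow(tx), params$het_rate)
  snp_rows <- list(); hap2 <- tx$seq
  for (i in which(n_snp > 0)) {
    g <- gene_of_id(tx$id[i])
    row <- reg[reg$gene == g, ]
    pos <- sample(seq(row$cds_start, row$cds_end), n_snp[i])
    s2 <- strsplit(tx$seq[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ref <- s2[p]
      alt <- sample(setdiff(BASES, ref), 1)
      s2[p] <- alt
      snp_rows[[length(snp_rows) + 1L]] <-
        data.frame(id = tx$id[i], gene = g, pos = p,
                   cds_pos = p - row$cds_start + 1L,
                   ref = ref, alt = alt, freq = 0.5, stringsAsFactors = FALSE)
    }
    hap2[i] <- paste(s2, collapse = "")
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(id = character(0), gene = character(0), pos = integer(0),
               cds_pos = integer(0), ref = character(0), alt = character(0),
               freq = numeric(0))

  ## abundances and read counts
  abundance <- stats::rlnorm(nrow(tx), meanlog = 0, sdlog = 1.2)
  w <- abundance * len
  total_reads <- params$total_reads %||%
    round(params$mean_depth * sum(len) / params$read_len)
  counts <- as.vector(stats::rmultinom(1, total_reads, w))

  ## emit SAM
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tx$id, len), con)
  qual <- strrep("I", params$read_len)
  cigar <- sprintf("%dM", params$read_len)
  for (i in seq_len(nrow(tx))) {
    if (counts[i] == 0) next
    starts <- sample.int(len[i] - params$read_len + 1L, counts[i], replace = TRUE)
    use_h2 <- stats::runif(counts[i]) < 0.5 & hap2[i] != tx$seq[i]
    src <- ifelse(use_h2, hap2[i], tx$seq[i])
    reads <- substring(src, starts, starts + params$read_len - 1L)
    writeLines(sprintf("%s_r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       tx$id[i], seq_len(counts[i]), tx$id[i], starts,
                       cigar, reads, qual), con)
  }
  list(path = path, snps = snps,
       abundance = data.frame(id = tx$id, abundance = abundance,
                              reads = counts, stringsAsFactors = FALSE))
}

## identity + score of two equal-length sequences
pair_identity <- function(sa, sb) {
  a <- strsplit(sa, "", fixed = TRUE)[[1]]
  b <- strsplit(sb, "", fixed = TRUE)[[1]]
  sum(a == b)
}

hit_row <- function(q, s, matches, len, frame = 0L) {
  bitscore <- max(2 * matches - len, 30)
  data.frame(query = q, subject = s,
             pct_identity = 100 * matches / len, aln_length = len,
             mismatches = len - matches, gap_opens = 0L,
             q_start = 1L, q_end = len, s_start = 1L, s_end = len,
             evalue = max(1e-180, 2 ^ (-bitscore / 4)), bitscore = bitscore,
             frame = frame, stringsAsFactors = FALSE)
}

#' Simulate similarity-search tables for the evolved sets
#'
#' Emits transcript-vs-transcript tables (A-vs-B, B-vs-A, A-vs-C,
#' C-vs-A) with one hit per true homology — paralogs produce competing
#' hits — plus per-species transcript-vs-reference-protein tables with
#' the frame column filled, and optional spurious hits at high E-value.
#'
#' @param triple from [plant_paralogs()] / [evolve_triple()].
#' @param dir output directory.
#' @return named list of file paths.
#' @export
simulate_similarity_tables <- function(triple, dir) {
  params <- triple$params
  set.seed(od_subseed(params$seed, "similarity"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- triple$truth$regions
  seqs <- stats::setNames(
    unlist(lapply(triple$species, function(s) s$seq)),
    unlist(lapply(triple$species, function(s) s$id)))

  tx_table <- function(sp_x, sp_y) {
    xs <- triple$species[[sp_x]]; ys <- triple$species[[sp_y]]
    rows <- list()
    for (i in seq_len(nrow(xs))) {
      g <- gene_of_id(xs$id[i])
      y_id <- paste0(sp_y, "_", g)
      partners <- y_id
      par_y <- triple$truth$paralogs
      partners <- c(partners, par_y$paralog_id[par_y$gene == g & par_y$species == sp_y])
      partners <- partners[partners %in% ys$id]
      for (p in partners) {
        m <- pair_identity(xs$seq[i], seqs[[p]])
        rows[[length(rows) + 1L]] <- hit_row(xs$id[i], p, m, nchar(xs$seq[i]))
      }
      if (stats::runif(1) < params$spurious_rate) {
        other <- sample(setdiff(ys$id, partners), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          query = xs$id[i], subject = other, pct_identity = round(stats::runif(1, 30, 45), 2),
          aln_length = 60L, mismatches = 35L, gap_opens = 2L,
          q_start = 1L, q_end = 60L, s_start = 1L, s_end = 60L,
          evalue = stats::runif(1, 0.5, 5), bitscore = round(stats::runif(1, 25, 34), 1),
          frame = 0L, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  prot_table <- function(sp) {
    xs <- triple$species[[sp]]
    rows <- lapply(seq_len(nrow(xs)), function(i) {
      g <- gene_of_id(xs$id[i])
      row <- reg[reg$gene == g, ]
      coding <- substr(xs$seq[i], row$cds_start, row$cds_end - 3L)
      prot <- translate_cds(coding)
      ref_prot <- translate_cds(substr(row$seq, row$cds_start, row$cds_end - 3L))
      m <- pair_identity(prot, ref_prot)
      out <- hit_row(xs$id[i], row$ref_protein, m, row$prot_len,
                     frame = (row$cds_start - 1L) %% 3L + 1L)
      out$q_start <- row$cds_start; out$q_end <- row$cds_end - 3L
      out$s_start <- 1L; out$s_end <- row$prot_len
      out
    })
    do.call(rbind, rows)
  }
  paths <- list()
  for (pair in list(c("A", "B"), c("B", "A"), c("A", "C"), c("C", "A"))) {
    nm <- paste0("tx_", pair[1], "_vs_", pair[2])
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    write_blast_tab(tx_table(pair[1], pair[2]), paths[[nm]])
  }
  for (sp in names(triple$species)) {
    nm <- paste0("prot_", sp)
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    write_blast_tab(prot_table(sp), paths[[nm]])
  }
  paths
}

#' Simulate gene-to-term annotation tables with planted enrichment
#'
#' Every gene draws a Poisson number of distinct terms; genes in
#' `core_genes` draw the `enriched_terms` with `enrich_mult`-fold
#' relative weight, planting enrichment detectable by the
#' hypergeometric test.
#'
#' @param gene_ids all annotated gene ids.
#' @param core_genes subset destined for core families.
#' @param n_terms vocabulary size (default 30).
#' @param enriched_terms character vector of planted terms (may be
#'   empty for a null table).
#' @param enrich_mult relative weight of planted terms in core genes
#'   (default 5).
#' @param terms_per_gene Poisson mean (default 2).
#' @param seed RNG seed.
#' @return data.frame: `gene`, `term`.
#' @export
simulate_annotation_tables <- function(gene_ids, core_genes = character(0),
                                       n_terms = 30L,
                                       enriched_terms = character(0),
                                       enrich_mult = 5, terms_per_gene = 2,
                                       seed = 1L) {
  if (n_terms < 1) stopf("n_terms must be >= 1")
  set.seed(od_subseed(seed, "annotations"))
  vocab <- sprintf("GO:%04d", seq_len(n_terms))
  if (!all(enriched_terms %in% vocab)) vocab <- union(vocab, enriched_terms)
  base_w <- rep(1, length(vocab))
  core_w <- base_w
  core_w[vocab %in% enriched_terms] <- enrich_mult
  rows <- lapply(gene_ids, function(g) {
    k <- min(length(vocab), 1L + stats::rpois(1, terms_per_gene - 1))
    w <- if (g %in% core_genes) core_w else base_w
    data.frame(gene = g, term = sample(vocab, k, prob = w), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a planted-partition protein-similarity graph
#'
#' All within-family node pairs are connected at `within_weight`;
#' between-family pairs carry a spurious edge of `between_weight` with
#' probability `between_frac`, mimicking the sparse off-target hits of
#' an all-against-all search (most unrelated pairs produce no hit at
#' all).  Species labels rotate over members so most families span the
#' species set.
#'
#' @param n_genes nodes (default 200).
#' @param n_families planted families (default 40).
#' @param within_weight,between_weight edge weights (defaults 1, 0.05).
#' @param between_frac probability that an unrelated pair has an edge
#'   (default 0.02).
#' @param n_species species labels to rotate (default 3).
#' @param seed RNG seed for the spurious edges.
#' @return list: `graph` (as [similarity_graph()] returns) and `truth`
#'   (data.frame `id`, `family`).
#' @export
simulate_family_graph <- function(n_genes = 200L, n_families = 40L,
                                  within_weight = 1, between_weight = 0.05,
                                  between_frac = 0.02, n_species = 3L,
                                  seed = 1L) {
  set.seed(od_subseed(seed, "family_graph"))
  ids <- sprintf("n%04d", seq_len(n_genes))
  fam <- rep(seq_len(n_families), length.out = n_genes)
  fam <- fam[order(fam)]
  species <- LETTERS[rep(seq_len(n_species), length.out = n_genes)]
  idx <- t(utils::combn(n_genes, 2))
  within <- fam[idx[, 1]] == fam[idx[, 2]]
  w <- ifelse(within, within_weight, between_weight)
  keep <- (within & w > 0) |
          (!within & w > 0 & stats::runif(nrow(idx)) < between_frac)
  edges <- data.frame(from = ids[idx[keep, 1]], to = ids[idx[keep, 2]],
                      weight = w[keep], stringsAsFactors = FALSE)
  list(graph = list(nodes = data.frame(id = ids, species = species,
                                       stringsAsFactors = FALSE),
                    edges = edges),
       truth = data.frame(id = ids, family = fam, stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs ancestors, evolution, paralogs, similarity tables, reads (for
#' species A) and annotations, writing FASTA/SAM/TSV files plus a truth
#' bundle, all derived from `params$seed`.
#'
#' @param params from [evol_params()].
#' @param dir output directory.
#' @return list with `files` (named paths), `triple` and `truth`
#'   (including planted SNPs and abundances).
#' @export
simulate_dataset <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anc <- simulate_ancestors(params)
  triple <- plant_paralogs(evolve_triple(anc))
  files <- list()
  for (sp in names(triple$species)) {
    files[[paste0("fasta_", sp)]] <- file.path(dir, paste0("species_", sp, ".fa"))
    write_fasta(triple$species[[sp]], files[[paste0("fasta_", sp)]])
  }
  files <- c(files, simulate_similarity_tables(triple, dir))
  reads <- simulate_reads(triple, "A", file.path(dir, "reads_A.sam"))
  files$sam_A <- reads$path
  ann <- simulate_annotation_tables(triple$truth$map$gene,
                                    core_genes = triple$truth$map$gene,
                                    seed = params$seed)
  files$annotations <- file.path(dir, "annotations.tsv")
  utils::write.table(ann, files$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- triple$truth
  truth$snps <- reads$snps
  truth$abundance <- reads$abundance
  list(files = files, triple = triple, truth = truth, params = params)
}
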