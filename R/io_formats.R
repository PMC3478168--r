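## Readers and writers for every external format the pipeline touches.
## Coordinates are 1-based inclusive at all file boundaries (BLAST/SAM
## convention) and 0-based half-open internally; the conversion happens
## here and in the delineation code, nowhere else.

#' Read a FASTA file into a transcript table
#'
#' Sequences are uppercased and U is mapped to T, so RNA-style input is
#' accepted.  Duplicate identifiers and empty sequences are errors: the
#' pipeline's orthology bookkeeping requires ids to be unique per species.
#'
#' @param path FASTA file.
#' @param species optional species label stored alongside each record.
#' @return a data.frame with columns `id`, `species`, `seq`.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stopf("duplicate FASTA ids: %s", paste(dups, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0)) {
    stopf("empty sequence for id: %s", paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stopf("non-ACGTN characters in sequence: %s", paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, species = species, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a transcript table to FASTA
#'
#' @param records data.frame with columns `id` and `seq` (as from
#'   [read_fasta()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

BLAST_COLS <- c("query", "subject", "pct_identity", "aln_length", "mismatches",
                "gap_opens", "q_start", "q_end", "s_start", "s_end",
                "evalue", "bitscore")

#' Parse a 12/13-column tabular similarity-search file
#'
#' The accepted dialect is BLAST `outfmt 6` with an optional 13th column
#' holding the query frame (used by translated searches; 0 for
#' nucleotide-vs-nucleotide).  Hits are returned in file order.
#'
#' @param path tab-separated hit table.
#' @return data.frame of hits with a `frame` column (`0` when the file had
#'   no frame column).
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), 13),
                                         c(BLAST_COLS, "frame")))
    out$query <- character(0); out$subject <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields)
  bad <- which(!(ncol_ok %in% c(12L, 13L)))
  if (length(bad)) stopf("malformed hit row at line %d (%d columns)", bad[1], ncol_ok[bad[1]])
  m <- matrix(unlist(lapply(fields, `[`, 1:13)), ncol = 13, byrow = TRUE)
  out <- data.frame(
    query = m[, 1], subject = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    frame = ifelse(is.na(m[, 13]), 0L, suppressWarnings(as.integer(m[, 13]))),
    stringsAsFactors = FALSE)
  num_bad <- which(is.na(out$evalue) | is.na(out$bitscore) | is.na(out$aln_length))
  if (length(num_bad)) stopf("malformed hit row at line %d (unparsable number)", num_bad[1])
  if (any(out$evalue < 0)) stopf("negative evalue at line %d", which(out$evalue < 0)[1])
  out
}

#' Write a hit table in the 13-column tabular dialect
#' @param hits data.frame as from [parse_blast_tab()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f\t%d",
                   hits$query, hits$subject, hits$pct_identity, hits$aln_length,
                   hits$mismatches, hits$gap_opens, hits$q_start, hits$q_end,
                   hits$s_start, hits$s_end,
                   formatC(hits$evalue, format = "e", digits = 2),
                   hits$bitscore, hits$frame)
  writeLines(lines, path)
  invisible(path)
}

## CIGAR helpers: parse "74M"-style strings into op/length pairs.
parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) stopf("unparsable CIGAR: %s", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op  = sub("^\\d+", "", toks))
}

cigar_query_len <- function(cig) sum(cig$len[cig$op %in% c("M", "I", "S", "=", "X")])

#' Parse a minimal SAM file
#'
#' Supports the dialect the simulator emits and the pileup consumes:
#' `@SQ` headers plus single-end mapped records with flags 0 or 16.
#' Unmapped records (flag bit 0x4) are skipped.  Target names are checked
#' against `@SQ` lines when any are present.
#'
#' @param path SAM text file.
#' @return data.frame with columns `read_id`, `flag`, `target_id`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq`.
#' @export
parse_sam_min <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[hdr][grepl("^@SQ", lines[hdr])]
  targets <- if (length(sq)) sub("^.*\tSN:([^\t]+).*$", "\\1", sq) else character(0)
  rec <- lines[!hdr & nzchar(lines)]
  if (!length(rec)) {
    return(data.frame(read_id = character(0), flag = integer(0),
                      target_id = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(rec, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    stopf("SAM record with fewer than 11 fields at line %d",
          which(!hdr & nzchar(lines))[which(lengths(fields) < 11)[1]])
  }
  m <- t(vapply(fields, `[`, character(11), 1:11))
  flag <- as.integer(m[, 2])
  keep <- bitwAnd(flag, 4L) == 0L
  out <- data.frame(read_id = m[keep, 1], flag = flag[keep],
                    target_id = m[keep, 3], pos = as.integer(m[keep, 4]),
                    mapq = as.integer(m[keep, 5]), cigar = m[keep, 6],
                    seq = m[keep, 10], stringsAsFactors = FALSE)
  if (length(targets) && nrow(out)) {
    unknown <- !(out$target_id %in% targets)
    if (any(unknown)) {
      stopf("SAM record %s maps to target absent from @SQ: %s",
            out$read_id[unknown][1], out$target_id[unknown][1])
    }
  }
  ## vectorized check for plain "<n>M" records; general CIGARs walked
  simple <- grepl("^\\d+M$", out$cigar)
  if (any(simple)) {
    ln <- as.integer(sub("M$", "", out$cigar[simple]))
    bad <- which(ln != nchar(out$seq[simple]))
    if (length(bad)) {
      stopf("CIGAR/sequence length mismatch for read %s",
            out$read_id[simple][bad[1]])
    }
  }
  for (i in which(!simple)) {
    cig <- parse_cigar(out$cigar[i])
    if (cigar_query_len(cig) != nchar(out$seq[i])) {
      stopf("CIGAR/sequence length mismatch for read %s", out$read_id[i])
    }
  }
  out
}

#' Write rows to a TSV report with a fixed column schema
#'
#' Percent columns (names ending in `_pct` plus `divergence_pct`) are
#' written with 2 decimals, matching how divergence is displayed; other
#' numeric columns use up to 6 significant digits.
#'
#' @param rows data.frame; its columns must be exactly `schema`.
#' @param schema character vector of expected column names, in order.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(rows, schema, path) {
  extra <- setdiff(names(rows), schema)
  if (length(extra)) stopf("unexpected report column: %s", extra[1])
  missing <- setdiff(schema, names(rows))
  if (length(missing)) stopf("missing report column: %s", missing[1])
  rows <- rows[, schema, drop = FALSE]
  fmt1 <- function(x, nm) {
    if (is.numeric(x) && grepl("(_pct|_pc)$|^pct_", nm)) {
      ifelse(is.na(x), "NA", sprintf("%.2f", x))
    } else if (is.numeric(x) && !is.integer(x)) {
      ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))
    } else as.character(x)
  }
  cols <- mapply(fmt1, rows, names(rows), SIMPLIFY = FALSE)
  body <- if (nrow(rows)) do.call(paste, c(cols, sep = "\t")) else character(0)
  writeLines(c(paste(schema, collapse = "\t"), body), path)
  invisible(path)
}

#' Write a phylogenetic tree to a Newick file
#'
#' @param tree an [ape::phylo] object with labeled tips and non-negative
#'   branch lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stopf("tree must be a phylo object")
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label)) {
    stopf("tree has an unlabeled leaf")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stopf("tree has a negative branch length")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every threshold used by the pipeline, with the values used throughout
#' the package documentation: reciprocal-best-hit minimum sequence length
#' 200 bp, reference-protein E-value cutoff 1e-5, minimum CDS 150 bp,
#' stop-codon search window +/-30 bp, UTR acceptance surrogate (block
#' >= 30 bp at >= 70% identity), MCL inflation 1.6, enrichment cutoff
#' 1e-5, category reporting minimum 5 members, RPKM class bounds 20/50,
#' SNP gates depth >= 10 / alt count >= 3 / alt frequency >= 0.2, and the
#' TN93 distance model.
#'
#' @return a named list of settings.
#' @export
default_config <- function() {
  list(
    min_len = 200L, prot_evalue = 1e-5, cds_min = 150L, stop_window = 30L,
    utr_min_block = 30L, utr_min_ident = 70, inflation = 1.6,
    enrich_alpha = 1e-5, min_category_members = 5L,
    rpkm_low = 20, rpkm_high = 50,
    snp_min_depth = 10L, snp_min_alt_count = 3L, snp_min_alt_freq = 0.2,
    distance_model = "TN93", seed = 1L, quiet = FALSE
  )
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; keys absent from the file keep their
#' [default_config()] values, unknown keys are an error.
#'
#' @param path YAML file.
#' @return a named list of settings.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stopf("unknown config key: %s", unknown[1])
  cfg[names(user)] <- user
  cfg
}
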