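## RPKM quantification and expression-class binning.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = raw_reads * 1e9 / (length * total_mapped)`.  `total_mapped`
#' is the number of mapped reads (records kept by [parse_sam_min()]),
#' not raw sequencer output.
#'
#' @param counts named numeric vector gene -> mapped read count.
#' @param lengths named numeric vector gene -> length in bp.
#' @param total_mapped total mapped reads across all genes.
#' @return data.frame: `gene_id`, `length`, `raw_reads`, `rpkm`.
#' @export
compute_rpkm <- function(counts, lengths, total_mapped) {
  genes <- names(lengths)
  if (is.null(genes)) stopf("lengths must be a named vector")
  if (any(lengths <= 0)) stopf("zero or negative gene length")
  if (total_mapped <= 0) stopf("total_mapped must be positive")
  raw <- counts[genes]
  raw[is.na(raw)] <- 0
  if (sum(raw) > total_mapped) stopf("counts exceed total_mapped")
  data.frame(gene_id = genes, length = unname(lengths),
             raw_reads = unname(raw),
             rpkm = unname(raw * 1e9 / (lengths * total_mapped)),
             stringsAsFactors = FALSE)
}

#' Assign expression classes by RPKM
#'
#' High when `rpkm > high`, low when `rpkm < low`, medium otherwise;
#' the boundary values themselves fall in medium so the three classes
#' partition the range.
#'
#' @param records data.frame from [compute_rpkm()].
#' @param low,high class bounds (defaults 20 and 50).
#' @return `records` with an added `expr_class` column.
#' @export
bin_expression <- function(records, low = 20, high = 50) {
  records$expr_class <- ifelse(records$rpkm > high, "high",
                        ifelse(records$rpkm < low, "low", "medium"))
  records
}

#' Gene and read shares per expression class
#'
#' @param records data.frame from [bin_expression()].
#' @return data.frame: `expr_class`, `n_genes`, `gene_fraction`,
#'   `n_reads`, `read_fraction`; fractions sum to 1 per dimension.
#' @export
read_share_by_class <- function(records) {
  if (nrow(records) == 0) stopf("no expression records")
  cls <- c("high", "medium", "low")
  n_genes <- vapply(cls, function(c) sum(records$expr_class == c), numeric(1))
  n_reads <- vapply(cls, function(c) sum(records$raw_reads[records$expr_class == c]),
                    numeric(1))
  data.frame(expr_class = cls, n_genes = n_genes,
             gene_fraction = n_genes / sum(n_genes),
             n_reads = n_reads,
             read_fraction = if (sum(n_reads) > 0) n_reads / sum(n_reads) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression stage from a SAM file and transcript lengths
#'
#' Counts each read once (the first reported alignment) and chains
#' [compute_rpkm()] and [bin_expression()].
#'
#' @param sam data.frame from [parse_sam_min()].
#' @param lengths named vector of transcript lengths in bp.
#' @param low,high RPKM class bounds.
#' @return data.frame of expression records with classes.
#' @export
expression_stage <- function(sam, lengths, low = 20, high = 50) {
  sam <- sam[!duplicated(sam$read_id), , drop = FALSE]
  counts <- table(sam$target_id)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  rec <- compute_rpkm(counts, lengths, total_mapped = nrow(sam))
  bin_expression(rec, low = low, high = high)
}
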