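#' Published whitefly divergence summary tables
#'
#' Per-class divergence summaries and pair-level alignment statistics
#' from the published three-way comparison of *Bemisia tabaci* Asia II 3,
#' MEAM1 and MED transcriptomes, bundled as plain TSV.  These printed
#' totals are inputs to the derived-ratio report columns
#' ([divergence_ratios()], [mean_aligned_length()]); the per-class rows
#' follow the same schema as [summarize_divergence()] output.
#'
#' @return list with `classes` (per region x site-class divergence,
#'   MEAM1 vs Asia II 3) and `pairs` (per-comparison alignment
#'   statistics).
#' @export
whitefly_reference <- function() {
  dir <- system.file("extdata", package = "orthodiv")
  list(classes = utils::read.delim(file.path(dir, "whitefly_divergence_classes.tsv"),
                                   stringsAsFactors = FALSE),
       pairs = utils::read.delim(file.path(dir, "whitefly_pair_summary.tsv"),
                                 stringsAsFactors = FALSE))
}
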