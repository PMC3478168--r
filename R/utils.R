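#' @keywords internal
"_PACKAGE"

## Stage logging goes to stderr so report streams on stdout stay clean.
od_log <- function(stage, ..., quiet = FALSE) {
  if (isTRUE(quiet)) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

## Derive a reproducible 32-bit sub-seed from a master seed and a label.
## Only used to decorrelate stages; all streams trace back to one seed.
od_subseed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Reverse complement for plain character vectors of A/C/G/T/N strings.
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
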