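## Codon-level lookups shared by the divergence, selection, SNP and
## simulation code.  Everything is precomputed once from the standard
## genetic code into package-local tables.

BASES <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

codon_aa <- function() {
  if (is.null(.codon_env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- chartr("U", "T", names(gc))
    .codon_env$aa <- gc
  }
  .codon_env$aa
}

all_codons <- function() names(codon_aa())

sense_codons <- function() {
  aa <- codon_aa()
  names(aa)[aa != "*"]
}

is_stop_codon <- function(codon) codon_aa()[codon] == "*"

## Substitute `base` at `pos` (1..3) of `codon`.
mutate_codon <- function(codon, pos, base) {
  paste0(substr(codon, 1, pos - 1), base, substr(codon, pos + 1, 3))
}

## Degeneracy of each position of each sense codon, computed by
## enumerating the three alternative bases: "nd" if every change alters
## the amino acid (a change to a stop codon counts as altering), "4d" if
## none does, "other" otherwise.
degeneracy_table <- function() {
  if (!is.null(.codon_env$deg)) return(.codon_env$deg)
  aa <- codon_aa()
  codons <- names(aa)
  deg <- matrix("other", nrow = length(codons), ncol = 3,
                dimnames = list(codons, NULL))
  for (cod in codons) {
    if (aa[cod] == "*") next
    for (pos in 1:3) {
      alts <- setdiff(BASES, substr(cod, pos, pos))
      alt_aa <- aa[vapply(alts, mutate_codon, "", codon = cod, pos = pos)]
      n_change <- sum(alt_aa != aa[cod])   # stop "*" != aa counts as change
      deg[cod, pos] <- if (n_change == 3L) "nd" else if (n_change == 0L) "4d" else "other"
    }
  }
  deg[codon_aa() == "*", ] <- "other"
  .codon_env$deg <- deg
  deg
}

## Fraction of the 3 single-base changes at each position that are
## synonymous (NG86 site fractions; changes to stops are nonsynonymous).
syn_fraction_table <- function() {
  if (!is.null(.codon_env$synfrac)) return(.codon_env$synfrac)
  aa <- codon_aa()
  codons <- names(aa)
  sf <- matrix(NA_real_, nrow = length(codons), ncol = 3,
               dimnames = list(codons, NULL))
  for (cod in codons) {
    if (aa[cod] == "*") next
    for (pos in 1:3) {
      alts <- setdiff(BASES, substr(cod, pos, pos))
      alt_aa <- aa[vapply(alts, mutate_codon, "", codon = cod, pos = pos)]
      sf[cod, pos] <- sum(alt_aa == aa[cod]) / 3
    }
  }
  .codon_env$synfrac <- sf
  sf
}

## Translate an in-frame nucleotide string; "X" for codons containing N.
translate_cds <- function(seq) {
  n <- nchar(seq) %/% 3
  cods <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- codon_aa()[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Positions (1-based, of first codon base) of in-frame stops.
inframe_stops <- function(seq, frame_offset = 0L) {
  n <- (nchar(seq) - frame_offset) %/% 3
  if (n <= 0) return(integer(0))
  starts <- frame_offset + 3L * (seq_len(n) - 1L) + 1L
  cods <- substring(seq, starts, starts + 2L)
  starts[cods %in% STOP_CODONS]
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}
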