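---
title: "Methods: comparative transcriptome divergence with orthodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative transcriptome divergence with orthodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

orthodiv compares the transcriptomes of three closely related species
(the motivating system is the *Bemisia tabaci* whitefly cryptic species
complex: the native Asia II 3 and the invasive MEAM1 and MED) from
assembled transcript sets and tabular similarity-search results.  The
pipeline has eight analysis stages: expression quantification (RPKM),
reciprocal-best-hit orthology with paralog filtering, CDS/UTR
delineation, site-class divergence, Ka/Ks estimation, protein-family
clustering with term enrichment, neighbor-joining phylogeny, and SNP
detection.  A ninth, first-class component is a sequence-evolution
simulator that generates all pipeline inputs with known ground truth.

# Orthology and region delineation

Candidate orthologs are reciprocal best hits by bitscore (bitscore, not
E-value, because it is database-size independent; E-values are used
only for thresholds).  Ties for best hit drop the query — the
conservative reading of "unambiguous".  Both members must be at least
`min_len` = 200 bp long (sequence length, not aligned length).  Pairs
are kept only when both members' best reference-protein hits (E < 1e-5)
name the same protein; a bitscore tie between different proteins makes
a member ambiguous and drops the pair.  This same-protein rule is the
paralog filter: a duplicated gene maps to the same protein as its
source but loses the reciprocal-best race to the less diverged copy.

CDS boundaries are projected from the protein hit: residue 1 maps to
transcript position `q_start - 3*(s_start - 1)`; the start codon is the
in-frame ATG nearest that projection (searched upstream within the
transcript first, then downstream within the aligned region — both
directions inclusive), and the stop codon is the in-frame
TAA/TAG/TGA nearest the projected reference stop within a +/-30 bp
window (ends inclusive; ties resolved upstream).  Both search-order
conventions are fixed choices where the underlying procedure is
otherwise ambiguous.  A missing start or stop sets a partial flag and
clips the CDS to the aligned region.  Negative-frame hits
reverse-complement the transcript first; all downstream coordinates
refer to the re-oriented sequence.  CDS shorter than 150 bp or with an
internal in-frame stop are removed.

Coordinates are 1-based inclusive everywhere, including internally —
the convention of the file formats themselves (BLAST, SAM) and of R;
conversions happen only at the point of arithmetic.

CDS pairs are aligned codon-aware: translations (terminal stop codon
removed) are globally aligned under BLOSUM62 with gap open 11 / extend
1, then back-mapped to nucleotides; gap columns are excluded.  UTRs are
aligned by local nucleotide alignment (match +2, mismatch -3, gap open
5 / extend 2) keeping the single best block.  The source study accepted
UTR pairs at E < 1e-30 from its search engine; this package does not
compute Karlin-Altschul statistics and instead requires an aligned
block of at least 30 bp at 70% identity or better (both configurable) —
a documented surrogate of comparable stringency.  Local alignment can
trim a terminal mismatch from a UTR block; at the default divergences
this biases UTR divergence by about a relative percent, well inside the
statistical tolerance used in the tests.

# Site-class divergence

Aligned columns are classified by region (5'UTR, CDS, 3'UTR),
degeneracy and CpG status.  A codon position is nondegenerate (nd) when
every base change alters the amino acid (changes to stop codons count
as altering) and fourfold degenerate (4d) when none does; the label is
assigned only when both species' codons agree, otherwise the column
falls into "other" — so nd and 4d are subsets of CDS, not a partition,
matching how such tables are reported.  A column is CpG when its base
participates in a CG dinucleotide in either full sequence (the partner
base may lie outside the aligned region); the union rule is symmetric
under species swap and static per sequence.  Columns containing N are
excluded from all tallies.

Pooled divergence is total substitutions over total compared sites.
The reported SE is the across-locus standard error (standard deviation
of per-locus divergences over the square root of the locus count),
because published tables of this kind show SEs roughly twice the
binomial value, implying per-locus dispersion; the binomial SE is
emitted alongside.  The %GC column is computed on the first species by
default (the published definition is unstated; the choice is recorded
in the report).  Transitions are A<->G and C<->T; everything else is a
transversion.

Per-pair homology is 100 minus per-pair CDS divergence.  Mean identity
is also grouped by annotation category; categories with fewer than 5
pairs are suppressed and output is sorted most-divergent first.  Two
candidate dispersion statistics (SD of per-pair divergence as a
proportion and as a percent) are emitted because the published
statistic's scale is ambiguous; neither is asserted against.

# Ka/Ks

The estimator is Nei-Gojobori (1986): per-codon synonymous-site
fractions by enumeration (averaged between the two sequences),
differences resolved by averaging over all minimal substitution paths,
excluding paths through stop codons; codon pairs whose every path is
blocked are skipped and counted.  Rates use the Jukes-Cantor correction
`K = -3/4 log(1 - 4p/3)`, undefined at `p >= 3/4`.  The source study
used the YN method of a standalone calculator; NG86 was chosen here
because it is fully specified and verifiable against brute-force path
enumeration — a documented deviation, with the same qualitative
behaviour at the low divergences involved.  Significance uses a Fisher
exact test of `[[Sd, S-Sd], [Nd, N-Nd]]` (differences versus remaining
sites by site type; the construction inside the original calculator is
unpublished, so this one is stated explicitly).  NG86 site counts are
real-valued and are rounded to integers for the exact test; the
rounding error is bounded by half a site.  The two-sided p sums all
hypergeometric table probabilities not exceeding the observed table's
probability, with a `1 + 1e-7` relative tie guard so that
floating-point noise cannot split exact ties.

# Protein families and enrichment

Translated genes (longest hit span per gene, at least 200 nucleotides —
the literal reading of the published length filter, about 66 residues)
form a similarity graph whose edge weights are the maximum bitscore
over the two hit directions.  Markov clustering uses inflation 1.6,
self-loops equal to each node's maximum incident weight, entry pruning
at 1e-12, and a convergence tolerance of 1e-8 with a 200-iteration cap;
clusters are the connected components of the limit matrix's support.
The iteration is invariant to node order and to uniform weight scaling.
Core families contain members of all three species.  Term enrichment in
the core set uses the exact hypergeometric upper tail with a raw cutoff
of 1e-5, as in the source methodology (no multiple-testing correction);
Bonferroni-adjusted values are reported in a side column for
transparency.

# Phylogeny

Three-way ortholog triples (one unambiguous partner per list) are
concatenated anchored on species A: columns aligned in both pairwise
CDS alignments, gap and N columns removed, genes in sorted id order.
Distances are closed-form TN93 by default (K2P and p-distance are also
available).  The source study used MEGA's Maximum Composite Likelihood;
TN93 is the closest closed-form model with the same "substitutions per
site" units — a documented substitution.  Trees come from Saitou-Nei
neighbor joining; for three taxa the branch lengths solve the
three-point system exactly, and negative branch lengths are clamped to
zero with a warning.  The three-taxon result is reported as the
unrooted star with branch lengths, which carries the same information
as any displayed rooting.

# Expression and SNPs

RPKM is `reads * 1e9 / (length * total_mapped)`, with `total_mapped`
the number of mapped reads (each read counted once, first alignment).
Expression classes are high (RPKM > 50), medium and low (RPKM < 20);
the boundary values 20 and 50, unassigned by the strict published
inequalities, go to medium so the classes partition the range.

SNP calling piles up reads over the orthologous CDS intervals (M/I/D
CIGAR operations; spliced alignment is unnecessary against
transcripts).  A site is called at depth >= 10 — the published gate —
plus two support gates added by this package and labelled as such:
alternate-allele count >= 3 and frequency >= 0.2, without which any
single discordant base at depth 10 would become a call.  The reference
allele is the assembled transcript base (the consensus).  Effects
substitute the alternate base into its codon: synonymous iff the amino
acid is unchanged; changes to stops are nonsynonymous; codons with N
are flagged undetermined.

# The simulator and what it does (not) emulate

`evol_params()` fixes the study conditions: 500 genes; CDS 300-900 bp
(multiples of 3) flanked by 60-200 bp 5'UTRs and 90-300 bp 3'UTRs;
branch lengths `t_A = 0.02`, `t_B = t_C = 0.005` substitutions/site
(one species about twice as far from the common ancestor, the
relationship reported for the whitefly complex); transition bias
`kappa = 4`; CpG transition-rate multiplier 6 — CpG hypermutability is
cytosine deamination, so only the transition channel is elevated,
which both raises CpG divergence and raises ts/tv at CpG sites, the
direction seen in real data; acceptance probabilities `f_nd = 0.1` for
amino-acid-changing proposals at nd sites (chosen to reproduce the
roughly ten-fold 4d/nd contrast) and `f_ns = 0.5` elsewhere; UTR rate
multiplier 1.2 (UTR divergence about twice the selection-suppressed
CDS value); 10% planted paralogs with doubled extra divergence; mean
0.2 planted heterozygous SNPs per gene at frequency 0.5 (the upper end
of the per-gene SNP rates reported across the three species); 74-bp
error-free reads at a 40x target mean depth with log-normal (sdlog
1.2) per-gene abundances.

Conventions that make the generator analytically checkable: CpG
context and CDS site classes are defined on the ancestor and frozen
(no re-evaluation after mutation), matching how sites are classified
downstream; proposals creating a stop codon — or destroying the
terminal stop — are always rejected, so the downstream internal-stop
filter cannot fire nondeterministically; at most one proposal per site
per branch (branch lengths are small, so multiple hits are second
order); all randomness derives from one master seed with per-gene
sub-seeds, making every output byte-reproducible.

What the simulator does not emulate: indels (so real alignment-error
modes are untested), sequencing errors (the SNP precision result is a
clean-separation property, not an error-robustness claim),
codon-usage and composition realism, recombination, and assembly
artifacts.  Passing tests therefore demonstrate correctness of the
computations under the stated generative model, not robustness to
every failure mode of real transcriptome data.

The similarity-table generator emits one hit per true homology with
identity measured from the sequences, bitscore increasing in matches,
competing hits for planted paralogs, and (by default 1% per query)
spurious hits at high E-value.  The planted-partition family graph
connects all within-family pairs at weight 1.0 and unrelated pairs at
weight 0.05 with probability 2% — an all-against-all search produces
no hit at all for most unrelated pairs, so the spurious edges are
sparse.

# Verification strategy and problem sizes

Every counting method is checked against an independent enumeration
oracle: degeneracy over all 61x61 sense-codon pairs at all positions;
NG86 sites and differences over all sense-codon pairs by explicit path
enumeration; hypergeometric tails against log-binomial sums over every
urn with population up to 60; the Fisher two-sided p exhaustively over
all margins with population up to 30 plus 400 sampled urns up to 60.
The Markov clustering is compared with a plain-loop reference
implementation of the same iteration and with planted-partition
recovery (adjusted Rand index).  Neighbor joining is checked for exact
reproduction of additive matrices.

The end-to-end recovery check runs the full pipeline on one simulated
500-gene study and compares all fifteen pooled per-class divergences
with a direct Monte-Carlo re-simulation of the mutation process
(independent code, about 10^6 site-replicates over the same
ancestors, classified with the enumeration oracles).  Agreement is
required within three combined standard errors
(`3 * sqrt(se_run^2 + se_mc^2)`), combining the run's binomial SE with
the oracle's Monte-Carlo SE — the oracle expectation is over mutation
randomness given the ancestors, and the run is one draw from that
process.  A closed-form per-site expectation is impossible here
because the downstream classes are defined on the evolved pair (union
CpG, both-codons-agree degeneracy), which couples neighbouring sites;
the Monte-Carlo oracle is the stated alternative.  Determinism is
checked by comparing two complete 150-gene report bundles byte for
byte; determinism is size-independent, so the smaller size only keeps
the suite brisk.

# Known limitations

The NG86/YN and TN93/MCL-distance substitutions above mean numeric
results are not expected to reproduce a YN-based or MEGA-based analysis
to the digit, only in structure and direction.  The UTR E-value
surrogate is a stringency proxy, not a calibrated equivalent.
Published headline numbers that depend on the real sequencing data and
historical database versions (pair counts, family counts, absolute SNP
counts) are outside what a simulation can or should reproduce; the
package instead reproduces every piece of in-table arithmetic and every
qualitative contrast those tables assert.
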