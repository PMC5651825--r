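---
title: "Methods: primary-transcriptome annotation and pan-genome analysis with drnatss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primary-transcriptome annotation and pan-genome analysis with drnatss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drnatss)
```

# The problem

Differential RNA sequencing (dRNA-seq) distinguishes genuine transcription
start sites (TSSs) from RNA processing sites by comparing two libraries
prepared from the same RNA: one treated with a terminator
5'-phosphate-dependent exonuclease (TEX+), which degrades processed,
5'-monophosphorylated transcripts while sparing primary,
5'-triphosphorylated ones, and an untreated control (TEX-). A genomic
position whose 5'-end read count is enriched in TEX+ over TEX- marks a
true initiation event. From a genome-wide TSS map one can then read off
the regulatory grammar of a bacterium: where transcription starts relative
to each open reading frame, what the housekeeping sigma-factor promoter
(-10/-35 boxes) looks like, how long 5' untranslated regions (UTRs) are,
and where the Shine-Dalgarno ribosome-binding site (RBS) sits. drnatss
implements that analysis chain as composable, tested R functions, plus a
comparative-genomics module that classifies protein families across
genomes into core / dispensable / unique categories and builds a
neighbour-joining pan-genome tree.

Genome-scale results from real dRNA-seq experiments depend on raw
sequencing data; the package therefore ships a synthetic-data generator
that plants a complete, known transcription architecture in a random
genome, so every stage can be validated against ground truth.

# The synthetic generator and what it emulates

`sim_config()` fixes the study conditions. The defaults describe a 200 kb
circular genome with 100 non-overlapping genes, one gene per equal slot,
alternating strand at random. Each gene receives, with probability 0.9, a
primary TSS at a sampled 5'UTR distance upstream of its start codon; with
probability 0.15 a weaker secondary TSS (0.3x the primary read strength)
lands further upstream in the same window. Around every planted TSS the
generator writes:

* a **-10 box** (consensus `TATAAT`) whose 3' end is 7 nt upstream of the
  TSS — the canonical sigma-70 register, and the centre of the 20-nt
  search window used downstream;
* with probability 0.7 a **-35 box** (`TTGACA`) separated from the -10 by
  a spacer drawn uniformly from 16-18 nt (spacer counted as the nt
  strictly between the boxes);
* a pyrimidine at **-1** with probability 0.86 and a purine at **+1**
  with probability 0.94 — the composition reported for bacterial primary
  transcriptomes;
* an **RBS** (`GGAGR`, R = A/G) at a 5-10 nt spacer from the start codon,
  when the UTR is long enough to hold it.

Every consensus base is independently replaced by a uniformly random base
with probability `per_base_mutation_rate` (default 0.05), which emulates
the sequence divergence of real promoters around their consensus.

5'UTR lengths are drawn from a two-component sampler: with probability
0.12 a uniform long tail on 100-250 nt (long, structured UTRs), otherwise
12 nt plus a negative binomial (mu 21, size 3), putting the modal length
in the low twenties of nt and the overall median near 35 nt. These mirror
the shape of published bacterial 5'UTR distributions (a sharp 20-29 nt
mode, roughly 88% below 100 nt); the exact component parameters are
generator choices, fixed once.

Antisense TSSs (default 10) are planted inside gene bodies on the
opposite strand, intergenic TSSs (default 10) in annotation-free gaps
verified to fall outside every classification window. Read counts are
Poisson: TEX+ mean 100 at a primary TSS and mean 100/10 in TEX-
(`tex_enrichment` 10), the inverted ratio at 50 processed 5'-end sites,
and a uniform Poisson background (mean 0.05/position) everywhere. Poisson
is the minimal count model; the generator deliberately does not model
library-size heterogeneity, positional autocorrelation of coverage,
sequencing error, or mapping ambiguity — so passing tests demonstrate
correctness of the algorithms, not robustness to every artefact of real
libraries.

All randomness flows from the single integer seed; identical
configurations give byte-identical FASTA/GFF3/bedGraph output.

# TSS detection

`call_tss()` marks a position as a candidate when its raw TEX+ 5'-end
count reaches `min_count` (default 10) and the pseudocounted ratio of
library-size-corrected TEX+ to TEX- counts reaches `min_enrichment`
(default 2). Counts are corrected to the mean depth of the two libraries
(so with equal totals the ratio is simply `(plus + 1)/(minus + 1)`; CPM
values are reported alongside). The pseudocount (default 1) keeps the
ratio finite at zero TEX- counts and shrinks enrichment estimates at low
coverage. Candidates within `cluster_window` (5 nt) on the same strand
merge; the position with the highest TEX+ count survives, ties resolving
to the most-upstream position strand-aware, and clusters may wrap across
the circular origin. These thresholds are declared defaults in the spirit
of published dRNA-seq pipelines rather than values taken from any one
study.

# Positional classification

`classify_tss()` gives each TSS exactly one label with precedence
P > S > I > A > N. Sense-strand TSSs within the window from 300 nt
upstream to 100 nt downstream of a start codon compete per gene: highest
TEX+ count wins primary (P), the rest are secondary (S). The downstream
bound is configurable (some studies use 150 nt; both are supported). A
TSS inside two genes' windows goes to the nearer start codon, ties to the
upstream gene — whether one TSS may serve two divergent genes is a
genuinely open convention, and the nearest-gene rule is this package's
declared choice. Remaining TSSs inside a sense-strand ORF are internal
(I), those opposite an ORF antisense (A), the rest intergenic (N). UTR
length is the distance from the TSS to the base before the start codon;
0 means leaderless, and negative values (P assigned downstream of the
start) are flagged.

# Motif discovery

`discover_motif()` is a ZOOPS (zero-or-one occurrence per sequence) EM
finder. Each window either contains one motif occurrence at an unknown
offset or is pure background. The E-step computes per-offset and absence
posteriors from the current position probability matrix, the fixed
background (pooled window composition), and the occurrence prior
(initialized at 0.8); the M-step re-estimates the matrix with pseudocounts
and the prior from the occurrence posteriors. By default the offset
distribution itself is also learned (a Dirichlet-smoothed
position-specific prior shared across sequences, in the spirit of MEME's
position-specific priors): promoter elements occupy a nearly fixed
register relative to the TSS, and sharing that information keeps an
isolated chance match at an implausible offset from out-scoring a
slightly degenerate genuine site. When sites really do sit at random
offsets the learned prior stays near uniform and the fit reduces to
plain ZOOPS; `learn_offset_prior = FALSE` restores the textbook model. Iteration stops when the
log likelihood moves by less than `tol` (1e-6) or after 200 iterations;
the best of 20 random restarts wins. Because promoter sites sit at a
nearly fixed register, EM can converge to an alignment shifted by a base
(a likelihood plateau); a post-fit refinement tries common shifts of +/-2
and keeps the alignment with the highest information content, preferring
no shift on ties. Sites are max-posterior offsets of windows with
occurrence posterior above 0.5 — that threshold is also what "motif
conserved at a TSS" means in the reported conservation fractions. The
reported PFM holds one-hot site counts plus 0.25 per base, so columns sum
to the site count plus one.

The -10 is sought in offsets -20..-1 relative to the TSS and the -35 in
-50..-21 (offset -1 is the base before the +1; there is no offset 0).
Significance is assessed by permutation: each window's bases are shuffled
independently, discovery is re-run, and the observed total information
content is compared with the permuted distribution,
`p = (1 + #{IC_perm >= IC_obs}) / (1 + n_perm)`. Permutation discovery
uses 2 restarts — the null statistic needs far less optimization effort —
and calibration tests match that effort in the observed fit so the test
is not anti-conservative.

# RBS search

`find_rbs()` scans offsets -17..+3 around each start codon for the best
match to the degenerate consensus `GGAGR`, scored in log2 odds against a
uniform background with near-one-hot columns; a hit must score within 2
bits of the perfect match, which in practice admits only consensus
matches (the R column accepts either purine). Matches are constrained to
end before the start codon, so the spacer (nt between the last RBS base
and the base before the codon) is non-negative. Windows reaching past
the TSS of short UTRs are truncated and flagged. Ties between
equal-scoring words resolve to the most upstream.

# GC skew and replication origin

`cumulative_gc_skew()` computes (G - C)/(G + C) in 1 kb windows tiled at
1 kb steps (the final window wraps the circle; window and step are
parameters with no canonical published values) and accumulates them. The
origin is reported at the window midpoint of the cumulative minimum and
the terminus at the maximum — the labelling follows from leading-strand
guanine excess accumulating from the origin onward, and is stated
explicitly because skew-plot services report both extrema without labels.
Bases other than A/C/G/T/N are rejected to keep the statistics
well-defined; N contributes to no window count.

# Pan-genome analysis

`score_pairs()` aligns every protein pair with Smith-Waterman (BLOSUM62,
gap open 11/extend 1) and keeps edges with raw score >= 50 and a
Karlin-Altschul E-value proxy <= 1e-10. The proxy uses fixed gapped
BLOSUM62 parameters (lambda 0.267, K 0.041) and query x subject search
space; full BLAST statistics (composition adjustment, finite-size
corrections) are out of scope, and at these thresholds the decision is
insensitive to that refinement. `mcl_cluster()` is a direct
implementation of Markov clustering: column-stochastic matrix with
max-edge self-loops, expansion (squaring), inflation (elementwise power
1.5, renormalize), pruning below 1e-5, iterated to a 1e-6 fixed point;
families are connected components of the converged structure, singletons
allowed. Inflation 1.5 keeps families from fragmenting at the 90%
identity regime the generator produces.

Families present in all genomes are core, in one genome unique, otherwise
dispensable; paralogs share a family and count once for presence but
individually in gene totals, which is what reconciles family counts with
gene counts. Genome-to-genome distance is Jaccard on family
presence/absence, and the tree is classic neighbour joining (Q-matrix
minimization, standard branch-length and reduction formulas, negative
branches clamped to zero and flagged). On additive matrices the
implementation reproduces the generating tree's path distances to 1e-9;
`ape::nj` serves as an independent cross-check in the test suite, never
as the implementation.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; bedGraph I/O converts
  from its 0-based half-open convention at the boundary.
* Windows and clusters wrap the circular chromosome.
* Zero-total libraries, empty sequences, constant skew profiles,
  non-symmetric distance matrices and out-of-bounds annotations raise
  errors rather than propagating silently.
* EM ties, merge ties and RBS score ties all have deterministic,
  documented tie-breaks, so fixed seeds give identical output.

# Problem sizes used in the tests

The test suite and the acceptance script run the generator at its default
scale (200 kb, 100 genes) for detection/classification, 100 kb with 50
fully promoter-equipped genes for motif recovery, 30-window null sets
with 99 permutations and 50 repeats for calibration, and 5 genomes x 60
families at 90% identity for the pan-genome stage. These sizes give
stable statistics (binomial noise on recovery rates well below the
asserted margins) while keeping a full run inside a few minutes on one
CPU.

# Known limitations

* The read model is Poisson with uniform background; real 5'-end profiles
  show overdispersion and position-dependent artefacts the generator does
  not emulate.
* The classifier assigns each TSS to one gene; divergent promoters
  driving two genes are split by the nearest-start rule.
* RBS scoring is consensus matching, not a full energy model of 16S
  pairing.
* The E-value proxy approximates BLAST statistics with fixed parameters.
* Operon structure is deliberately out of scope: a gene transcribed only
  from an upstream operon promoter has no primary TSS of its own.
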