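---
title: "Quantifying intron retention and its epigenomic context: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention and its epigenomic context: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retainr)
```

# The problem

Intron retention (IR) is the splicing outcome in which an intron survives into
the mature mRNA. Because most retained introns introduce premature termination
codons, IR typically routes transcripts into nonsense-mediated decay and so
acts as a negative regulator of gene expression, prominently during myeloid
differentiation (promyelocytes versus granulocytes). Measuring IR from
RNA-seq is deceptively simple and riddled with biases: intronic coverage is
contaminated by embedded non-coding RNAs, inflated or deflated by regions
where short reads cannot be placed uniquely, and noisy at single-base
resolution. `retainr` implements an IR discovery pipeline that confronts each
of these biases explicitly, a differential-IR test suited to digital counts,
and window-based metaprofiles that relate retention to DNA methylation and
MeCP2-like ChIP occupancy around splice junctions.

# The quantification model

For each annotated intron we measure two abundances per sample.

**Splice abundance** counts aligned fragments whose alignment gap (cigar `N`
operation) spans the intron. Three tallies are kept: fragments spliced
exactly from donor to acceptor; fragments whose gap starts at the donor but
ends elsewhere (alternative acceptors downstream); and fragments whose gap
ends at the acceptor but starts elsewhere. The one-sided tallies each include
the exact fragments, and the larger of the two is used as the splice
abundance — the most generous estimate of how often this intron is removed.

**Intronic abundance** is a trimmed mean of per-base fragment coverage over
the intron's *measurable* area. Two classes of positions are excluded before
any depth is collected, not zero-filled:

* positions overlapped by an annotated feature of a different gene (miRNAs
  and snoRNAs hosted in introns are the classic offenders — their expression
  is not intron retention);
* positions flagged by the mappability screen described below.

The surviving per-base depths are sorted and the highest and lowest 30% of
values (`floor(0.30 * n)` from each end) are discarded before averaging,
suppressing residual spikes and dips.

The **IR ratio** is then

$$\mathrm{IR} = \frac{\text{intronic abundance}}
{\text{intronic abundance} + \text{splice abundance}},$$

a number in [0, 1]; an intron with IR ratio ≥ 0.10 is called *retained*. An
intron with no measurable area, or with zero evidence on both sides (0/0),
is *not assessable* — a state deliberately distinct from an IR ratio of 0.

# The mappability screen

Whether a position is measurable is decided by a synthetic-read experiment on
the reference itself: reads of 70 bp are taken every 10 bp across the genome,
every second read is reverse-complemented, and a single deterministic base
substitution (A→C, C→G, G→T, T→A, N→A) is planted at read position 34
(0-based). Each read is re-aligned allowing one mismatch; it is credited only
if exactly one location genome-wide matches, which is then necessarily its
origin. Under this geometry an interior base can be overlapped by at most 7
reads; any base with fewer than 5 credited reads is poorly mappable, and
maximal runs of failing bases form the mask. The rule is absolute, so
chromosome ends — where fewer than 5 overlapping reads are geometrically
possible — are always masked; at toy scale no genes are placed there, and at
genome scale telomeric ends are not gene-bearing either.

The screen is a pure function of the genome and its parameters (no seed).
The built-in aligner is an exhaustive two-strand substring search, exact and
practical up to a few hundred kilobases; for larger genomes the same reads
can be exported as FASTA, aligned externally, and re-imported as SAM, with
the same crediting rule applied to the external alignments.

# Differential IR

The change of an intron between two samples is assessed with the
Audic–Claverie statistic for digital counts: given count $x$ with
normalisation total $N_1$, the posterior probability of count $y$ under total
$N_2$ is

$$p(y\,|\,x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative-binomial mass in $y$ with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The two-sided p-value doubles the smaller of
$P(Y \le y\,|\,x)$ and $P(Y \ge y\,|\,x)$, capped at 1. All tail sums are
accumulated in log space, and the smaller tail is always obtained by direct
summation — taking it as `1 - larger` would cancel catastrophically below
about `1e-16`, which matters because the pipeline screens thousands of
introns for tiny p-values. Counts up to at least $10^6$ are handled; beyond
the double-precision floor the p-value underflows gracefully to 0.

A call is significant only if all three cutoffs hold: p-value < 0.05; splice
abundance strictly above 10 in *both* samples; and IR ratio strictly above
0.1 in at least one sample. The bias between increased and decreased calls is
tested with an exact binomial against 0.5 (doubled smaller tail). No
multiple-testing correction is applied by default, matching the raw-p
convention of this filter; Benjamini–Hochberg is available behind the
`adjust` flag.

**Which counts feed the test.** The contrast is deliberately pluggable. The
default (`strategy = "local"`) takes $x, y$ as the rounded intronic
abundances and $N_i$ as intronic + splice abundance per sample, so the test
asks whether the intron's share of its local fragment pool shifted. The
alternative (`"library"`) normalises by the summed splice abundance of the
whole sample. We default to the local pool because it is insensitive to
global expression shifts of the host gene, which would otherwise masquerade
as differential retention; the exact normalisation used historically for this
filter is not documented, so both readings remain available.

Two properties of the test worth knowing: the exchangeable core is the
posterior mass itself ($p(y|x) = p(x|y)$ at equal totals), but the doubled
two-sided p is directional — swapping the samples can change it, which is
inherent to conditioning on one observation; and because intronic abundance
is a trimmed mean rather than a raw count, its sampling variance is at or
below Poisson scale, making the test conservative on null data (observed
type-I rate ≈ 0.01–0.02 at α = 0.05 in the packaged null simulation).

# Junction metaprofiles

Per-CpG methylation is summarised as a beta value (methylated reads over
total coverage), with sites kept only above the coverage floor of five reads
(strictly more than five). Around each anchor — the 5′ junction, the 3′
junction, or the intron midpoint — the ±100 bp region is divided into 20
non-overlapping 10-bp sub-windows. Windows are non-overlapping because the
paired test below needs independent-ish bins that tile the region exactly; a
sliding/overlapping mode exists behind the `window`/`flank` parameters for
exploration. Within a window, all valid sites from all introns of a stratum
are pooled and averaged (sum of betas over number of sites). Pooling, rather
than averaging per intron first, weights CpG-dense introns more but keeps the
estimator well-defined in sparse windows; both readings are defensible and
pooling matches the sum-over-count definition used throughout.

Orientation is strand-aware: profiles of minus-strand introns are flipped so
that negative offsets are always the exonic side of a 5′ junction. Midpoint
windows are clipped to the intron span so short introns do not re-count
junction-adjacent signal. Interval-valued signal (ChIP fold enrichment per
peak) contributes its value once to every window its interval overlaps.

The retained-versus-non-retained contrast is a classical paired t-test across
the ≤ 20 window-mean pairs (pairs with an empty window on either side are
dropped; fewer than 3 complete pairs is an error; a zero-variance non-zero
difference is reported as degenerate rather than given a fabricated p).

# Feature statistics

Retained versus non-retained comparisons of intron length, GC fraction and
CpG density use Welch's t-test by default — the safer choice under unequal
variances; the pooled-variance Student form is available via `var_equal`.
Gene-distance clustering compares edge-to-edge same-chromosome gaps between
IR-gene pairs against seeded random pairs. Intron adjacency within genes is
tested by permutation, re-placing each gene's retained introns uniformly
among its intron slots, which controls for gene length and intron number.
The IR–expression association is an ordinary least-squares regression of log
expression on IR level with an F-test.

# The simulator

Every statistical claim above is exercised on synthetic data generated by the
package itself. The simulator plants multi-exon genes on alternating strands
of a random chromosome, separated by 500 bp spacers; exons are 150–250 bp,
introns 200–400 bp — compact but in realistic proportion for a toy genome.
Transcript molecules retain each intron independently with the intron's true
retention fraction *r*; fragments of fixed length 70 bp start uniformly over
molecule positions, with molecules weighted by their number of valid starts,
as fragmentation of an RNA pool would weight them. Spliced introns become `N`
gaps in the emitted alignments. Fragments are emitted pre-aligned (SAM)
because read alignment is outside the pipeline's scope.

Methylation counts are Binomial draws around a baseline beta of 0.8, dropped
by a configurable dip (default 0.3) within 100 bp of the junctions of truly
retained introns, with Poisson coverage (mean 30); ChIP fold enrichment
mirrors the beta shape on a positive scale. Duplicated blocks can be planted
to stress the mappability screen, and foreign ncRNA features inside chosen
introns to stress the exclusion logic.

What the simulator does *not* model — and what passing tests therefore do not
certify on real data: sequencing errors and bisulfite-conversion failure,
fragment-length variability, expression-level heterogeneity across genes,
alternative transcript structures within a gene, and multi-mapping reads in
the RNA-seq input (assumed removed by the upstream aligner).

# Numerical and design choices

* Coordinates are 1-based closed GRanges internally; all exchange formats
  (BED, junction boundary coordinates, FASTA sub-sequences) are 0-based
  half-open at the interface.
* Intron deduplication is per gene; identical gaps in overlapping genes stay
  distinct records, because IR is reported per gene. Introns sharing one
  boundary (alternative 5′/3′ sites) are kept as separate records.
* Intronic abundances are rounded half-up before the count test, which
  requires integers.
* The trim count is `floor(0.30 * n)` per side — deterministic, and exact
  for the stated fraction at large n.
* The fold change of IR ratios uses a pseudocount of 0.01 on both sides.
* Problem sizes in the packaged checks — 2 kb screening genomes, 201×201
  count grids, 200 recovery replicates of 5,000 fragments, 50-intron
  two-sample screens — were chosen as the smallest sizes at which the
  geometric and statistical claims are non-trivially exercised.

# Known limitations

* The built-in aligner's uniqueness rule (exactly one two-strand hit at ≤ 1
  mismatch) does not model gapped or quality-aware alignment; external
  aligners may credit slightly different read sets near repeat boundaries.
* Group comparisons pool each group into single count vectors; there is no
  replicate-aware dispersion estimation.
* The midpoint anchor is `start + floor(width/2)`; for introns narrower than
  200 bp the clipped midpoint profile overlaps the junction flanks' windows
  in genomic space, and the two views should not be treated as independent.
* Single-end fragments are the default; paired-end input collapses to
  fragment-level counting upstream of this package.
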