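---
title: "Junction walking: annotation-free splicing events from junction count tables"
author: "JunctionWalker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction walking: annotation-free splicing events from junction count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(JunctionWalker)
```

## The method

RNA-seq spliced alignments yield, for every sample, a table of splice
junctions — introns identified by chromosome, first and last intronic base,
and strand — with the number of split reads supporting each. JunctionWalker
analyzes alternative splicing directly from such tables, without any
transcript annotation, which makes it equally sensitive to annotated and
unannotated exons and lets thousands of samples be summarized from one
junction matrix rather than from raw reads.

The search is exon-centric and local. Junctions are grouped by shared start
or end coordinate, and closed loops are traced through alternating runs of
exons and introns that return to their starting coordinate. A binary
splicing event is a pair of loops sharing an exclusion condition. Four
patterns are recognized:

* **Cassette exon** — inclusion junctions $(s, a)$ and $(d, e)$ around an
  exon $[a+1,\,d-1]$, against the exclusion junction $(s, e)$ joining the
  flanks directly.
* **Alternative splice-site exon group** — cassette variants under the same
  exclusion junction that share exactly one splice site (same start,
  different ends, or vice versa); they are merged into one event listing all
  variant intervals (connected components under the shared-boundary
  relation).
* **Linked exons** — a chain of exons whose consecutive junctions all exist,
  skipped as a unit by one exclusion junction. Chains are capped at
  `max_linked` (default 3) exons: linked exons behave as one in/out unit and
  longer chains grow combinatorially without adding interpretable events.
* **Mutually exclusive exons (MXE)** — two non-overlapping exons between
  common flanking coordinates, each with both path junctions present, with
  no junction bridging them. The direct flank-to-flank junction need not
  exist.

Exon intervals are inferred purely from junction coordinates: the bases
between consecutive inclusion junctions. All coordinates are 1-based and
fully closed, with junction start/end denoting the first and last intronic
base (the STAR and junction-database convention); BED output converts to
0-based half-open.

### Filters, tie-breaks and non-binary regions

* A junction takes part in discovery when it has at least `min_reads`
  (default 5) reads in at least `min_samples` (default 1) samples. The
  defaults are deliberately permissive; both are exposed.
* A bridge junction between two candidate MXE partners vetoes the pair
  unless its total count is below `mxe_noise_frac` (default 0.01) times the
  mean total of the four path junctions — strict absence is brittle under
  alignment noise. The bridge lookup consults the unfiltered table, so a
  bridge too weak to pass the presence filter can still veto.
* When the flank-to-flank junction coexists with an MXE pair, three
  cassette-shaped loops appear under it: each partner exon alone and the
  union path spanning both. All are readings of the same mutually exclusive
  structure; the MXE interpretation takes precedence and the cassette
  readings are suppressed (logged with reason codes
  `cassette_suppressed_by_mxe` and `cassette_spans_mxe`).
* Flank pairs offering more than two mutually exclusive paths, chains
  longer than `max_linked`, and cassette-shaped candidates whose putative
  exon contains further junctions are non-binary regions: they are dropped,
  never guessed at, and recorded in the `diagnostics()` table.
* Events are deduplicated by a stable id
  (`type|chrom|span|exon intervals`), sorted by genomic position, and are
  invariant to input row and sample order. Discovery runs per chromosome on
  genomic coordinates only; strand is carried along solely to orient the
  motif analysis, and junctions of unknown strand participate in discovery
  but are excluded there.

## Percent spliced-in

For each event and sample, let $\bar I$ be the mean of the
inclusion-path junction counts and $\bar X$ the exclusion-side count (the
single exclusion junction, or for MXE the mean of the partner path's two
junctions). Then

$$\mathrm{PSI} = 100 \cdot \frac{\bar I}{\bar I + \bar X}.$$

The mean (not the sum) keeps a two-junction inclusion path commensurate with
a one-junction exclusion path: every molecule that includes the exon
contributes split-read evidence at *each* inclusion junction, so per-junction
counts — not their sum — estimate inclusion abundance. Because conventions
differ between tools, the aggregation is a single switch
(`mode = "mean" | "sum" | "min"`). For alternative splice-site groups,
$\bar I$ sums the per-variant path means: each variant contributes its own
path, and the shared junction carries all variants' molecules, so this
statistic measures total inclusion mass of the group rather than a
per-variant molecule fraction.

Cells with fewer than `min_informative` (default 15) informative reads
($\mathrm{round}(\bar I + \bar X)$) are *missing*, never 0: at low depth the
ratio is dominated by sampling noise and a spurious extreme PSI is worse
than a blank. MXE PSI is reported once, for the upstream exon; the partner's
value is its complement and emitting it separately would only add a
perfectly anti-correlated row.

## Group summaries and specificity calls

Group means are taken over non-missing cells only, and a group mean is
reported only when at least `min_group_n` (default 2) samples were
informative. A *specificity call* uses the min-gap contrast: an event is
enriched in group $G$ when $\mathrm{mean}(G)$ exceeds the **maximum** mean
among all other informative groups by at least `threshold` (default 50 PSI
points), and depleted under the mirrored criterion. Comparing against the
best other group — not a pooled mean — means a single other cell type
sharing the exon vetoes the call, which is the intended reading of
"specific". Events with fewer than `min_groups_informative` (default 3)
informative groups are skipped. The procedure is descriptive thresholding on
PSI; no p-values are attached, deliberately, since the quantity of interest
is the magnitude of the usage contrast, not its mere non-zeroness.

## Splice-site motif windows

For every stranded event exon, four windows are read in transcript
orientation: intronic flanks of `intronic_flank` (default 1000) bases and
exonic margins of `exonic_flank` (default 50) bases at the donor (5'SS) and
acceptor (3'SS). Exonic windows are clipped at half the exon length so the
two splice sites never double-count a short exon; all windows truncate (not
pad) at chromosome ends. Motif occurrences are counted with overlap
(sliding by one base; clustered motifs are the signal of interest, so
overlapping hits must all count), U and T are interchangeable, and each
occurrence is assigned to the positional bin of its first base. Positions
are signed distances from the splice site — intron negative, exon positive —
binned at `bin_width` 25 bases (40 intronic + 2 exonic bins per side).

Counts are normalized per exon and divided by the same statistic over a
baseline exon set (by default all protein-coding annotation exons shorter
than 400 bases, deduplicated) to give per-bin enrichment, defined only where
the baseline is positive. `proximalEnrichment()` averages the enrichment of
the intronic bins within 200 bases of the splice site — the window where
UAG-binding regulators such as MSI1 leave their footprint upstream exons
they activate. A motif set can be scanned and summed in one profile;
`motif = "ptbp1"` is a preset for the CU/UC repeats ({CUCU, UCUC}) bound by
PTBP1. Both the per-exon means and raw totals are emitted, since published
positional plots differ in which they show.

## The synthetic-data generator

Every statistical claim the package makes is tested against data with known
truth, generated by the package itself.

A locus is one splicing unit: constitutive flanking exons around the
alternative structure of one event type, with explicit transcript chains.
For each locus and sample, the informative read total $n$ is drawn from a
negative binomial with mean `depth` (default 200) and overdispersion
`dispersion` (default 0.2; Poisson at 0) — public-archive run accessions
vary widely in depth, and 0.2 gives a realistic coefficient of variation of
about 0.5 at depth 200. Each junction on the inclusion path then draws an
independent $\mathrm{Binomial}(n, \psi)$ count and each exclusion-side
junction $\mathrm{Binomial}(n, 1-\psi)$, emulating split-read coverage: a
molecule crosses every junction on its path, and per-junction read sampling
is approximately independent given the molecule count. Variant-specific
junctions of an alternative splice-site group get $\psi/m$ for $m$ variants
while their shared junction keeps $\psi$. Constitutive junctions draw
Poisson(`depth`). Optional noise junctions appear at `noise_rate` expected
per locus with Poisson(1) counts, placed at least 20 bases from any true
splice site so they can never silently redefine a planted event. All
randomness flows from the single truth seed.

`simulateGenome()` writes one uniform-random chromosome per locus with
canonical GT..AG dinucleotides (in transcript orientation) at every
junction, plants motif copies at requested signed offsets, and scrubs
accidental occurrences of the motif and its reverse complement from the
background (`scrub = FALSE` keeps the chance-rate background, which is what
a baseline exon set should be profiled on). The GTF contains all exons as
protein-coding features, with event exons optionally withheld to exercise
the annotated/unannotated flag.

What the generator does *not* emulate — and what green tests therefore do
not demonstrate about real data: alignment artifacts other than sparse
random noise junctions, GC- or structure-driven junction-count bias,
mappability differences between junctions, intron retention, and genuinely
non-binary splicing structures beyond the bridged/skip variants described
above. The discovery layer would see such effects only through the
presence filters and the noise fraction.

## Problem sizes and numerical choices in the test suite

The suite validates discovery against an independent brute-force oracle
that enumerates exon triples and quadruples directly from transcript
structures; 500 random loci (up to 8 exons and 6 transcripts each, mixed
types, strands, extra flanks, MXE skip/bridge variants) must match with
100% set equality. PSI calibration uses depth 200 with 100 replicate
samples at inclusion rates 5–95%, requiring mean absolute error under 2 PSI
points and exactness at 0 and 100. Specificity recovery plants one group at
$\psi = 0.9$ against nine at $0.05$ (20 samples per group) and requires
exact recovery with zero calls on matched null simulations of 200 events.
Motif recovery plants eight TAG copies per exon in the proximal-200 donor
window of 50 loci and requires all counts in the planted bins and at least
two-fold enrichment over a chance-rate baseline. These sizes keep each
check well-powered while the whole suite stays fast enough to run on every
change.

Remaining numerical details: ties in alternative splice-site variant order
are broken by (start, end); events sort by (chromosome, span, id); PSI is
stored at full precision and serialized to one decimal on the 0–100 scale;
the minimum intron length on ingest is 20 bases (configurable), which
removes sub-intron alignment artifacts before they enter the coordinate
index.

## Limitations

Complex, nested splicing decisions are out of scope by design: only the
four binary patterns are emitted, everything else is surfaced in the
diagnostics table rather than guessed at. PSI inherits the biases of
junction counts; no GC or secondary-structure correction is attempted.
Specificity calling is descriptive and has no error-rate control beyond the
threshold itself. The motif layer reports enrichment ratios, not
significance.
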