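---
title: "Quantifying intron retention and splice-junction usage across a diurnal time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intron retention and splice-junction usage across a diurnal time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclesplice)
```

## The problem

Bulk RNA-seq sampled repeatedly over a light–dark cycle captures not only
expression changes but changes in how transcripts are spliced. cyclesplice
quantifies two complementary views of alternative splicing from
coordinate-sorted spliced alignments:

* **Percent intron retention (PIR)** for the *constitutive introns* of each
  gene — the gaps left between a gene's merged exons, which are spliced out
  of every annotated isoform. Retention of such an intron is direct
  evidence of an unspliced or alternatively processed transcript.
* **Percent spliced-in (PSI)** for *local splicing events* — groups of
  splice junctions that share one boundary (a common donor or a common
  acceptor). Within an event, each junction's PSI is the fraction of the
  event's reads that support that junction.

Downstream, events are classified by type (alternative 5′/3′ splice site,
exon skipping, complex) and reading-frame consequence, inserted sequence is
scanned for premature stop codons in all six frames, and the PSI/PIR
trajectories are clustered over the time course with k-means.

## The PIR model

For one intron and one sample, five quantities are counted from primary
alignments with mapping quality at least `min_mapq` (default 10):

* `sj` — reads whose alignment gap excises the intron *exactly*; a
  near-miss gap is evidence about a different junction, not about this
  intron's retention;
* `ie5`, `ie3` — ungapped reads crossing the exon–intron boundary at the
  donor and acceptor splice site, requiring at least `min_anchor`
  (default 10) aligned positions on *both* sides of the boundary;
* `intron_reads` — reads with any aligned position inside the intron;
* `intron_cov` — mean per-base aligned depth over the intron.

Counts are averaged across the replicates of each timepoint (so they may be
fractional) and then a filter cascade decides whether the intron is
quantifiable at that timepoint: `sj >= 5`, `ie5 >= 2` and `ie3 >= 2`,
`intron_cov >= 1.0`, and `intron_reads >= 5`. For quantified cells

$$\mathrm{PIR} = \frac{\#IE_5 + \#IE_3}{\#IE_5 + \#IE_3 + \#SJ}.$$

Two boundary cases have exact policies. An intron with `sj >= 5` and *no*
boundary-crossing reads at all is fully spliced: PIR is exactly 0.0
(status `spliced_only`). An intron with `sj < 5` has insufficient evidence:
its PIR is missing (`NA`, status `insufficient`). A compatibility switch
(`insufficient_as_zero = TRUE`) reports such cells as 0.0 instead; the
default is `NA` because missing cells are what the clustering step removes.
Cells whose boundary evidence is present but below the filters (for
example `ie5 = 1`) are also `insufficient`: the cascade defines
quantifiability, and 0.0 is reserved for the genuinely all-spliced case.

The PIR matrix keeps introns whose maximum PIR across timepoints is at
least 0.05, adds a pseudo-count of 0.001 to every non-missing cell, and
leaves insufficient cells `NA`.

## The PSI model

Junctions are extracted from every alignment gap whose flanking aligned
segments are each at least `min_overhang = 8` reference positions long,
keeping gaps between 10 and 3000 nt (the intron-length range of the
compact genomes this is designed for). Three noise filters follow: a
junction must be seen in *every* replicate of at least one timepoint, must
reach 2 supporting reads in some sample, and must not have either
splice-site base inside an annotated repeat interval.

Junctions of one gene sharing their genomic start form one event, and
junctions sharing their end form another, so a junction can participate in
up to two events — one per boundary. This shared-boundary grouping is this
package's own definition of a local splicing event. PSI is the plain read
proportion within the event; a sample with zero event reads has undefined
PSI for every junction of the event. The junction with the highest mean
PSI across samples with data is `canonical`, the rest `alternate`, with a
deterministic tie-break toward the lower genomic coordinate. Events are
kept only if some alternate exceeds PSI 0.05 in at least one sample *and*
some alternate has at least 2 reads in at least one sample.

The PSI matrix has one row per alternate junction, one column per
timepoint (replicate-mean PSI), and the exact pseudo-count 0.0001 in cells
with no data.

## Event consequences

For a non-complex event the top alternate is compared to the canonical
junction. If the alternate spans at least one whole annotated exon the
canonical does not span, the event is exon skipping and the length
difference is the skipped exon length; otherwise the event is an
alternative donor or acceptor (Alt 5′/Alt 3′, assigned with respect to the
gene's strand) and the difference is the distance between the two varying
boundaries. Events with more than one alternate above PSI 0.05 are
`complex` and excluded from frame classification. The frame class is
`preserving` exactly when the difference is divisible by 3; a preserving
insertion of $3n$ nt adds $n$ residues (for example, 177 nt adds 59).
When the alternate junction excises *less* than the canonical one, the
retained genomic interval is reported and its sequence can be scanned for
stop codons in the three forward and three reverse-complement frames
(`scan_ptc()`); codons containing `N` never count as stops. Only the
standard genetic code is used.

Mean PSI of frame-preserving versus frame-disrupting events is compared
with a two-sided Wilcoxon rank-sum test. R's `wilcox.test()` has no exact
treatment of ties, so for small samples (at most ~2×10⁵ arrangements) the
permutation distribution of the rank sum is enumerated exactly; larger
samples use the normal approximation. Bonferroni correction multiplies by
the number of tests in the batch; significance is declared at corrected
p < 0.01.

## Time-course clustering

Rows with any missing cell are removed first (their count is reported).
K-means uses Lloyd iterations with Euclidean distance and keeps the best
of 25 random initialisations by total within-cluster sum of squares; the
seed (default 42) makes runs bit-reproducible. The number of clusters is
*reported, not auto-selected*: `elbow_curve()` computes the within-cluster
sum of squares over k = 1..20 and the analyst chooses k, because the elbow
of these curves is rarely sharp and the biologically meaningful k depends
on the phase structure of the experiment. If a matrix has fewer distinct
row profiles than the requested k, every cluster is pure and the total
within-cluster sum of squares is 0.

Timepoints are ordered by agglomerative clustering of the centroid columns
(Euclidean distance, complete linkage — chosen for compact, balanced
clusters; neither choice is forced by the data and both are arguments).
Per-cluster summaries report mean, standard deviation, standard error
(SD/√n, 0 for singleton clusters) and a normal-approximation confidence
interval (mean ± z·SE); at the default 95% level z ≈ 1.96. Expression
context is a per-gene fold change of RPKM against the gene's mean across
timepoints; all-zero genes are reported as missing rather than dividing by
zero.

Phases follow the diurnal convention: timepoints 1–10 are Light G1, 11–15
(including half-hour points) S–M, 16–24 Dark G1. A matrix row "occurs" in
a phase when its value strictly exceeds the pseudo-count at one or more of
the phase's timepoints — pseudo-filled cells denote absence by
construction.

## The synthetic-data generator

`sim_design()` describes a toy genome whose defaults mirror a diurnal
cell-cycle experiment: 28 timepoints (hours 1–24 with half-hour points
between 11 and 15), two replicates per timepoint, 100 nt single-end reads,
300 reads per gene per sample, 300 nt exons and a 250 nt canonical intron.
Two gene shapes exist:

* **ir genes** (exon–intron–exon): each fragment comes from the
  intron-retained isoform with probability r(t), otherwise from the
  spliced isoform;
* **psi genes** (one donor, two acceptors): each fragment comes from the
  shorter-intron alternate isoform with probability p(t). The default
  acceptor offsets mix frame-preserving (177) and frame-disrupting (50,
  91) distances.

Default trajectories alternate two archetypes — dark-high (0.05/0.1 in
the light hours, 0.6/0.8 in the dark) and flat (0.3/0.5) — so that phase
logic, filter behaviour and cluster recovery are all exercised. Reads are
placed uniformly along the chosen isoform, spliced reads carry gaps
exactly at the isoform's junctions, and 10% of reads are emitted with
MAPQ 0 to exercise the mapping-quality filter (the rest have MAPQ 60).

Uniform placement gives the observed metrics closed-form expectations
recorded in the truth table. With read length $L$, anchor $a$, spliced
length $L_s$ and retained length $L_r$, a spliced-isoform read yields an
exact-gap junction read with probability $q_{sj} = (L-1)/(L_s-L+1)$ and a
retained-isoform read crosses a given boundary with
$q_{ie} = (L-2a+1)/(L_r-L+1)$, so

$$\mathbb{E}[\widehat{\mathrm{PIR}}] \approx
  \frac{r\,2q_{ie}}{r\,2q_{ie} + (1-r)\,q_{sj}},$$

and analogously for PSI with the two isoform lengths. These expectations
are what the tests compare observed values against, within three
binomial standard errors of the observed evidence count.

What the generator does *not* emulate: sequencing errors, quality-score
structure, paired-end fragments, multi-mapping ambiguity beyond the MAPQ
decoys, overlapping genes, or non-uniform coverage. Passing tests
therefore demonstrate the correctness of the counting, filtering and
clustering logic under clean alignments — not robustness to aligner
artefacts on real libraries.

## Numerical and design choices

* Internal coordinates are 0-based half-open with a single conversion at
  each parser (GFF3 1-based inclusive, BED as-is), so interval arithmetic
  needs no ±1 adjustments.
* Exons are pooled across all transcripts of a gene before merging, and
  touching exons merge, so no zero-length intron can arise.
* Introns of a gene overlapping another gene's exons are kept but flagged
  (`overlaps_gene_exon`) rather than silently dropped.
* A read with several gaps contributes one `sj` count to every intron it
  excises exactly; a read gapped at an intron cannot simultaneously count
  as boundary evidence there, because no contiguous aligned segment of it
  spans the boundary.
* Duplicate alignments are not removed; coverage counts every aligned
  record, including the intra-intron portions of boundary reads.
* Replicate averaging precedes the filter cascade.
* Junction extraction applies no MAPQ floor by default; the MAPQ filter
  belongs to the intron-retention counts.
* `elbow_curve()` shares one seed policy across k so curves are
  comparable; the non-increasing shape is a property of restarts, not of
  single Lloyd runs.
* Problem sizes in the test-suite simulations (hundreds to a few thousand
  reads per gene and sample, 2–6 timepoints) were chosen as the smallest
  scales at which the binomial standard errors make the recovery
  assertions sharp.

## Known limitations

* Event grouping by a shared boundary is a deliberate simplification of
  graph-based local-splicing-variation definitions; nested or multi-exon
  variations appear as several pairwise events.
* PSI here is a plain read proportion with no posterior smoothing, so
  low-coverage samples have noisy PSI; the event filters are the only
  guard.
* Exitrons (introns entirely inside annotated exons) are out of scope by
  construction: only gaps between merged exons are quantified.
* The six-frame stop scan asks whether a stop exists in *every* frame of
  the inserted sequence; it does not model which frame is translated, nor
  NMD triggering rules.
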