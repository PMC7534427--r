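# cyclesplice

Alternative-splicing quantification for time-course RNA-seq, built for
compact genomes (short introns, dense gene models) sampled repeatedly over
a diurnal or cell-cycle experiment with replicated timepoints. It serves
analysts who have coordinate-sorted spliced alignments (BAM), a GFF3
annotation and a sample sheet, and want per-timepoint intron-retention and
junction-usage values they can filter, classify and cluster.

Two metrics sit at the core:

* **PIR (percent intron retention)** for each constitutive intron — the
  gaps between a gene's merged exons. From reads that splice the intron
  out exactly (#SJ), cross the exon–intron boundary at the 5′ or 3′ splice
  site with ≥ 10 aligned bases on both sides (#IE₅, #IE₃), lie in the
  intron body (#I), and from the intron's mean coverage, replicate-averaged
  counts pass a filter cascade (#SJ ≥ 5; #IE₅, #IE₃ ≥ 2; coverage ≥ 1.0;
  #I ≥ 5) and then

  PIR = (#IE₅ + #IE₃) / (#IE₅ + #IE₃ + #SJ).

  Fully spliced introns (#SJ ≥ 5, no boundary reads) get PIR exactly 0.0;
  introns with #SJ < 5 are `NA`.

* **PSI (percent spliced-in)** for local splicing events — junctions of a
  gene sharing a donor or acceptor boundary. PSI of a junction in a sample
  is its share of the event's reads; the junction with the highest mean
  PSI is *canonical*, the others *alternate*. Junction filters
  (reproducibility across replicates, ≥ 2 reads, no repeat overlap) and
  event filters (alternate PSI > 0.05 and alternate reads ≥ 2 somewhere)
  remove noise.

On top of the matrices (introns/alternate junctions × timepoints, with
exact pseudo-counts 0.001 / 0.0001): event classification (Alt 5′/Alt 3′,
exon skipping, complex), frame-preservation by divisibility of the length
difference by 3, a six-frame stop-codon scan of inserted sequence, diurnal
phase occurrence, Wilcoxon comparison of PSI between frame classes, and
k-means clustering of trajectories with elbow diagnostics, hierarchical
timepoint ordering and per-cluster summaries. A synthetic spliced-read
simulator with analytic ground truth makes the whole pipeline testable
without any external data.

## Worked example

Simulate four genes — two with intron-retention trajectories, two with
alternative-acceptor PSI trajectories (one frame-preserving 177 nt apart,
one frame-disrupting 50 nt apart) — over five timepoints with two
replicates each, then run both pipelines:

```r
library(cyclesplice)

design <- sim_design(n_ir_genes = 2, n_psi_genes = 2,
                     timepoints = c(2, 8, 14, 20, 23), depth = 800,
                     seed = 42)
sim   <- simulate_dataset(design, "demo")
genes <- load_annotation(sim$gff3)

pir <- run_pir(sim$samples, genes)
pir$matrix
#> # PIR matrix: 2 rows x 5 timepoints (pseudo-count 0.001)
#> # A tibble: 2 × 6
#>   intron_id    TP2    TP8  TP14  TP20  TP23
#>   <chr>      <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 g01:1     0.0611 0.0556 0.641 0.643 0.614
#> 2 g02:1     0.349  0.366  0.373 0.298 0.355

psi <- run_psi(sim$samples, genes, repeats = load_repeats(sim$bed))
psi$matrix
#> # PSI matrix: 2 rows x 5 timepoints (pseudo-count 0.0001)
#> # A tibble: 2 × 6
#>   row_id                      TP2    TP8  TP14  TP20  TP23
#>   <chr>                     <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 g03:L3500|chrS:3500-3573 0.0824 0.0720 0.715 0.789 0.725
#> 2 g04:L4850|chrS:4850-5050 0.509  0.501  0.457 0.480 0.517
```

Gene `g01` was simulated dark-high (retention 0.05 in the light hours,
0.6 in the dark): its PIR rises from ~0.06 at TP2/TP8 to ~0.64 at
TP14–TP23. (The observed values sit slightly above the simulated rates
because boundary reads and exact-gap reads are captured with different
probabilities; the simulator's truth table carries the exact expected
values.) Gene `g02` is flat at 0.3, and the PSI rows behave the same way
for junction usage. Event classification and clustering:

```r
classify_events(psi$psi, genes)[, c("event_id", "event_type", "delta_nt",
                                    "frame_class", "n_inserted_aa")]
#>    event_id event_type delta_nt frame_class n_inserted_aa
#> 1 g03:L3500       Alt3      177  preserving            59
#> 2 g04:L4850       Alt5       50  disrupting            NA

fit <- kmeans_cluster(drop_incomplete_rows(pir$matrix), 2)
fit
#> k-means clustering of 2 PIR trajectories into k = 2 clusters
#> cluster sizes: 1, 1
#> total within-cluster SS: 0 (of total SS 0.218501)
```

The 177 nt alternate acceptor is frame-preserving (177 = 3 × 59) and
inserts 59 residues; the 50 nt one disrupts the frame. `tidy()`,
`glance()` and `autoplot()` work on the k-means fit, `elbow_curve()` /
`plot_elbow()` produce the within-cluster sum-of-squares diagnostic, and
`cluster_summary()` gives per-cluster per-timepoint mean/SD/SE/CI.

A thin command-line wrapper over the same functions ships at
`inst/cli/cyclesplice.R` with subcommands `derive-introns`, `pir`, `psi`,
`classify`, `cluster` and `simulate`.

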