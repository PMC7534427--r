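# Toy gene on chr1 spanning (0,1000), '+': junctions are grouped within it.
toy_gene <- tibble::tibble(
  gene_id = "g1", chrom = "chr1", strand = "+", start = 0L, end = 1000L,
  n_exons = 2L,
  exons = list(tibble::tibble(start = c(0L, 900L), end = c(100L, 1000L)))
)

test_that("junction extraction honours overhang and length bounds", {
  reads <- dplyr::bind_rows(
    make_read("ok", 80L, "20M100N20M"),       # anchors 20/20
    make_read("short_left", 95L, "5M100N35M"),  # 5 < 8 overhang
    make_read("too_long", 80L, "20M3001N20M"),
    make_read("too_short", 80L, "20M9N20M"),
    make_read("at_limit", 80L, "20M3000N20M")
  )
  jx <- extract_junctions(write_reads_bam(reads, chrom_len = 10000), "s1")
  expect_equal(nrow(jx), 2)
  expect_setequal(jx$end - jx$start, c(100L, 3000L))
  expect_true(all(jx$count == 1))
})

test_that("junction extraction equals the brute-force gap enumerator", {
  set.seed(201)
  for (rep in 1:5) {
    reads <- random_reads(300, pos_range = 600)
    jx <- extract_junctions(write_reads_bam(reads, chrom_len = 2000), "s")
    oracle <- oracle_junctions(reads)
    got <- dplyr::arrange(jx[, c("start", "end", "count")], start, end)
    want <- dplyr::arrange(oracle, start, end)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("reproducibility, support and repeat filters act independently", {
  design <- toy_design(c("TP1", "TP2"))
  jx <- function(start, end, sample_id, count) {
    tibble::tibble(chrom = "chr1", start = start, end = end,
                   sample_id = sample_id, count = count)
  }
  junctions <- dplyr::bind_rows(
    # seen in both replicates of TP1, well supported: survives
    jx(100L, 200L, c("TP1_R1", "TP1_R2"), c(3L, 2L)),
    # seen only in replicate 1 of each timepoint: removed
    jx(100L, 250L, c("TP1_R1", "TP2_R1"), c(5L, 5L)),
    # both replicates but max count 1: removed
    jx(100L, 300L, c("TP1_R1", "TP1_R2"), c(1L, 1L)),
    # both replicates, supported, but donor inside a repeat: removed
    jx(400L, 500L, c("TP1_R1", "TP1_R2"), c(4L, 4L))
  )
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t395\t405", bed)
  repeats <- load_repeats(bed)
  kept <- filter_junctions(junctions, design, repeats)
  expect_setequal(unique(kept$end), 200L)
  # each filter alone removes exactly its target
  no_repeat <- filter_junctions(junctions, design)
  expect_setequal(unique(no_repeat$end), c(200L, 500L))
  relaxed <- filter_junctions(junctions, design, repeats, min_reads = 1)
  expect_setequal(unique(relaxed$end), c(200L, 300L))
  expect_error(filter_junctions(junctions, design[, -3]), "replicate")
})

test_that("filter_junctions is monotone in min_reads", {
  set.seed(202)
  design <- toy_design(c("TP1", "TP2"))
  junctions <- tidyr::expand_grid(
    start = seq(100L, 1000L, by = 100L), sample_id = design$sample_id
  ) |>
    dplyr::mutate(chrom = "chr1", end = start + 80L,
                  count = rpois(dplyr::n(), 2))
  n_kept <- function(mr) {
    nrow(dplyr::distinct(filter_junctions(junctions, design,
                                          min_reads = mr),
                         start, end))
  }
  counts <- vapply(1:6, n_kept, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events group junctions by shared boundary within a gene", {
  junctions <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 150L, 700L),
    end = c(200L, 250L, 200L, 800L),
    sample_id = "s1", count = 5L
  )
  events <- group_events(junctions, toy_gene)
  # shared donor (start 100) event and shared acceptor (end 200) event;
  # junction (100,200) belongs to both; lone junction (700,800) to none
  expect_setequal(unique(events$event_id), c("g1:L100", "g1:R200"))
  expect_equal(sum(events$event_id == "g1:L100"), 2)
  expect_equal(sum(events$event_id == "g1:R200"), 2)
  expect_false("chr1:700-800" %in%
                 events$junction_id[events$event_id == "g1:L100"])
  # a junction outside every gene span is dropped with a message
  outside <- dplyr::mutate(junctions, start = start + 5000L,
                           end = end + 5000L)
  expect_message(ev2 <- group_events(outside, toy_gene), "dropped")
  expect_equal(nrow(ev2), 0)
})

test_that("PSI is the read proportion and sums to one where defined", {
  design <- toy_design("TP1")[1:2, ]
  junctions <- tibble::tibble(
    chrom = "chr1", start = c(100L, 100L, 100L),
    end = c(200L, 250L, 200L),
    sample_id = c("TP1_R1", "TP1_R1", "TP1_R2"),
    count = c(9L, 1L, 5L)
  )
  events <- group_events(junctions, toy_gene)
  psi <- compute_psi(events, junctions, design)
  r1 <- psi[psi$sample_id == "TP1_R1", ]
  expect_equal(sort(r1$psi), c(0.1, 0.9))
  r2 <- psi[psi$sample_id == "TP1_R2", ]
  expect_equal(sort(r2$psi), c(0, 1))
  expect_equal(sum(r1$psi), 1, tolerance = 1e-9)
  # a sample with zero event reads has undefined PSI
  empty_design <- tibble::tibble(sample_id = "TP9_R1", timepoint = "TP9",
                                 replicate = 1L)
  psi_none <- compute_psi(events, junctions[0, ], empty_design)
  expect_true(all(is.na(psi_none$psi)))
})

test_that("PSI sums to one across many random events", {
  set.seed(203)
  design <- toy_design(c("TP1", "TP2"))
  junctions <- tidyr::expand_grid(
    end = seq(200L, 800L, by = 50L), sample_id = design$sample_id
  ) |>
    dplyr::mutate(chrom = "chr1", start = 100L,
                  count = rpois(dplyr::n(), 3))
  events <- group_events(junctions, toy_gene)
  psi <- compute_psi(events, junctions, design)
  sums <- psi |>
    dplyr::group_by(event_id, sample_id) |>
    dplyr::summarise(total = sum(psi), reads = sum(count),
                     .groups = "drop")
  with_reads <- sums[sums$reads > 0, ]
  expect_true(all(abs(with_reads$total - 1) < 1e-9))
})

test_that("roles pick the highest mean PSI with a coordinate tie-break", {
  design <- toy_design("TP1")[1:2, ]
  make_psi <- function(counts1, counts2) {
    junctions <- tibble::tibble(
      chrom = "chr1", start = 100L, end = c(200L, 250L),
      sample_id = "TP1_R1", count = c(counts1, counts2)
    )
    events <- group_events(junctions, toy_gene)
    annotate_roles(compute_psi(events, junctions, design))
  }
  psi <- make_psi(8L, 2L)
  expect_equal(unique(psi$role[psi$end == 200L]), "canonical")
  expect_equal(unique(psi$role[psi$end == 250L]), "alternate")
  # exact tie: lower coordinate junction wins
  tie <- make_psi(5L, 5L)
  expect_equal(unique(tie$role[tie$end == 200L]), "canonical")
  expect_equal(sum(tie$role == "canonical"), 1 * 2)  # one per sample row
})

test_that("event noise filters require an informative alternate", {
  design <- toy_design("TP1")[1:2, ]
  build <- function(canon, alt) {
    junctions <- tibble::tibble(
      chrom = "chr1", start = 100L, end = c(200L, 250L),
      sample_id = "TP1_R1", count = c(canon, alt)
    )
    events <- group_events(junctions, toy_gene)
    annotate_roles(compute_psi(events, junctions, design))
  }
  # alternate PSI 0.04 (< 0.05): dropped
  low_psi <- filter_events(build(96L, 4L))
  expect_equal(nrow(low_psi), 0)
  # alternate PSI 0.3 but a single read: dropped
  low_reads <- filter_events(build(2L, 1L), min_alt_reads = 2)
  expect_equal(nrow(low_reads), 0)
  # alternate PSI 0.2 with 3 reads: retained
  ok <- filter_events(build(12L, 3L))
  expect_gt(nrow(ok), 0)
  # monotone in both thresholds
  expect_equal(nrow(filter_events(build(12L, 3L), min_alt_psi = 0.5)), 0)
  expect_equal(nrow(filter_events(build(12L, 3L), min_alt_reads = 4)), 0)
})

test_that("the PSI matrix averages replicates and pseudo-fills nulls", {
  design <- toy_design(c("TP1", "TP2", "TP3"))
  junctions <- tibble::tibble(
    chrom = "chr1", start = 100L, end = rep(c(200L, 250L), 3),
    sample_id = c("TP1_R1", "TP1_R1", "TP1_R2", "TP1_R2", "TP2_R1",
                  "TP2_R1"),
    count = c(8L, 2L, 6L, 4L, 9L, 1L)
  )
  events <- group_events(junctions, toy_gene)
  psi <- annotate_roles(compute_psi(events, junctions, design))
  mat <- build_psi_matrix(psi, design)
  expect_equal(names(mat), c("row_id", "TP1", "TP2", "TP3"))
  alt_row <- mat[grepl("250", mat$row_id), ]
  # replicate mean of PSI 0.2 and 0.4
  expect_equal(alt_row$TP1, 0.3)
  # TP2 has one replicate with data
  expect_equal(alt_row$TP2, 0.1)
  # TP3 never observed: exact pseudo-count
  expect_identical(alt_row$TP3, 0.0001)
  # rows are alternate junctions only
  expect_false(any(grepl("\\|chr1:100-200$", mat$row_id) &
                     grepl("L100", mat$row_id)))
})
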