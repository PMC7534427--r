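# Build a role-annotated PSI table directly so classification is tested in
# isolation from alignment handling.
fake_psi <- function(junctions, strand = "+", gene_id = "g1",
                     anchor_side = "left", samples = c("s1", "s2")) {
  # junctions: tibble(start, end, psi) with the first row canonical
  anchor <- if (anchor_side == "left") junctions$start[1] else
    junctions$end[1]
  tidyr::expand_grid(junctions, sample_id = samples) |>
    dplyr::mutate(
      event_id = paste0(gene_id, ":", toupper(substr(anchor_side, 1, 1)),
                        anchor),
      gene_id = gene_id, chrom = "chr1", strand = strand,
      anchor_side = anchor_side, anchor = anchor,
      junction_id = paste0("chr1:", start, "-", end),
      count = round(psi * 100),
      mean_psi = psi,
      role = rep(c("canonical", rep("alternate", nrow(junctions) - 1)),
                 each = length(samples))
    )
}

gene_with_exons <- function(exons, strand = "+") {
  tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = strand,
    start = min(exons$start), end = max(exons$end),
    n_exons = nrow(exons), exons = list(exons)
  )
}

simple_gene <- gene_with_exons(
  tibble::tibble(start = c(0L, 500L), end = c(100L, 600L))
)

test_that("alternative splice-site classes follow the varying boundary", {
  # shared start, varying acceptor on '+': Alt3
  psi <- fake_psi(tibble::tibble(start = 100L, end = c(200L, 250L),
                                 psi = c(0.8, 0.2)))
  cons <- classify_events(psi, simple_gene)
  expect_equal(cons$event_type, "Alt3")
  expect_equal(cons$delta_nt, 50L)
  expect_equal(cons$frame_class, "disrupting")
  # no insertion: the alternate excises more than the canonical
  expect_true(is.na(cons$inserted_start))

  # same event on '-': the shared left boundary is the acceptor, so Alt5
  psi_m <- fake_psi(tibble::tibble(start = 100L, end = c(200L, 250L),
                                   psi = c(0.8, 0.2)), strand = "-")
  expect_equal(classify_events(psi_m, simple_gene)$event_type, "Alt5")

  # shared end, varying donor on '+': Alt5
  psi_d <- fake_psi(tibble::tibble(start = c(100L, 150L), end = 250L,
                                   psi = c(0.7, 0.3)),
                    anchor_side = "right")
  cons_d <- classify_events(psi_d, simple_gene)
  expect_equal(cons_d$event_type, "Alt5")
  # alternate intron is shorter: interval (100,150) retained by alternate
  expect_equal(cons_d$inserted_start, 100L)
  expect_equal(cons_d$inserted_end, 150L)
})

test_that("exon skipping is detected by whole-exon containment", {
  gene <- gene_with_exons(tibble::tibble(
    start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)
  ))
  # alternate (100,400) spans exon (200,300); canonical (100,200) does not
  psi <- fake_psi(tibble::tibble(start = 100L, end = c(200L, 400L),
                                 psi = c(0.9, 0.1)))
  cons <- classify_events(psi, gene)
  expect_equal(cons$event_type, "ES")
  expect_equal(cons$delta_nt, 100L)
  expect_equal(cons$frame_class, "disrupting")
})

test_that("multiple significant alternates make an event complex", {
  psi <- fake_psi(tibble::tibble(start = 100L, end = c(200L, 250L, 300L),
                                 psi = c(0.5, 0.3, 0.2)))
  cons <- classify_events(psi, simple_gene)
  expect_equal(cons$event_type, "complex")
  expect_equal(cons$frame_class, "complex_excluded")
  # with one alternate below significance it is a plain Alt event
  psi2 <- fake_psi(tibble::tibble(start = 100L, end = c(200L, 250L, 300L),
                                  psi = c(0.66, 0.30, 0.04)))
  expect_equal(classify_events(psi2, simple_gene)$event_type, "Alt3")
})

test_that("frame class depends only on divisibility by three", {
  expect_equal(frame_class(177), "preserving")
  expect_equal(frame_class(3), "preserving")
  expect_equal(frame_class(1), "disrupting")
  expect_equal(frame_class(c(0, 2, NA)),
               c("preserving", "disrupting", NA))
})

test_that("a frame-preserving 177-nt insertion yields 59 residues", {
  psi <- fake_psi(tibble::tibble(start = 100L, end = c(400L, 223L),
                                 psi = c(0.7, 0.3)))
  cons <- classify_events(psi, simple_gene)
  expect_equal(cons$delta_nt, 177L)
  expect_equal(cons$frame_class, "preserving")
  expect_equal(cons$n_inserted_aa, 59L)
  expect_equal(cons$inserted_start, 223L)
  expect_equal(cons$inserted_end, 400L)
})

test_that("frame class is invariant to which junction is called canonical", {
  pair <- tibble::tibble(start = 100L, end = c(400L, 223L),
                         psi = c(0.7, 0.3))
  swapped <- pair[2:1, ]
  d1 <- classify_events(fake_psi(pair), simple_gene)$delta_nt
  d2 <- classify_events(fake_psi(swapped), simple_gene)$delta_nt
  expect_equal(d1, d2)
})

test_that("six-frame stop scan matches an independent translator", {
  expect_true(all(scan_ptc("")[1, 1:6] == FALSE))
  # frozen hand translation: GCT GCT GCT and its reverse complement
  # AGC AGC AGC contain no stop in any frame
  frozen <- scan_ptc("GCTGCTGCT")
  expect_false(any(as.logical(frozen[1, 1:6])))
  expect_false(frozen$all_six)

  # sequence found by randomized search, verified with Biostrings
  # translation in all six frames
  set.seed(301)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    if (oracle_all_six_stops(s)) break
  }
  expect_true(scan_ptc(s)$all_six)

  # random-sequence agreement with the oracle, frame by frame
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:40, 1),
                      replace = TRUE), collapse = "")
    expect_equal(scan_ptc(s)$all_six, oracle_all_six_stops(s))
  }
  expect_error(scan_ptc("ACGU"), "non-nucleotide")
})

test_that("N-containing codons are never stops", {
  expect_false(any(as.logical(scan_ptc("TNATAN")[1, 1:3])))
})

test_that("reverse-complementing swaps the forward and reverse flags", {
  set.seed(302)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))
    )
    a <- scan_ptc(s)
    b <- scan_ptc(rc)
    expect_identical(unname(unlist(a[1, c("f1", "f2", "f3")])),
                     unname(unlist(b[1, c("r1", "r2", "r3")])))
    expect_equal(a$all_six, b$all_six)
  }
})

test_that("phase occurrence uses a strict threshold per phase", {
  design <- tibble::tibble(timepoint = paste0("TP", c(2, 12, 18)),
                           phase = c("LightG1", "SM", "DarkG1"))
  mat <- tibble::tibble(
    row_id = c("dark_only", "light_sm", "absent"),
    TP2 = c(1e-4, 0.2, 1e-4),
    TP12 = c(1e-4, 0.3, 1e-4),
    TP18 = c(0.5, 1e-4, 1e-4)
  )
  attr(mat, "pseudo") <- 1e-4
  occ <- phase_occurrence(mat, design)
  expect_equal(occ$phases[[1]], "DarkG1")
  expect_setequal(occ$phases[[2]], c("LightG1", "SM"))
  expect_length(occ$phases[[3]], 0)
  # union property: occurrence of a row-wise max is the union of sets
  merged <- tibble::tibble(
    row_id = "merged",
    TP2 = max(mat$TP2[1:2]), TP12 = max(mat$TP12[1:2]),
    TP18 = max(mat$TP18[1:2])
  )
  attr(merged, "pseudo") <- 1e-4
  occ_m <- phase_occurrence(merged, design)
  expect_setequal(occ_m$phases[[1]],
                  union(occ$phases[[1]], occ$phases[[2]]))
})

test_that("diurnal phases partition the 24-hour cycle", {
  expect_equal(diurnal_phases(c(1, 10, 11, 11.5, 15, 16, 24)),
               c("LightG1", "LightG1", "SM", "SM", "SM", "DarkG1",
                 "DarkG1"))
})

test_that("the frame-class rank-sum test matches exact enumeration", {
  # identical distributions: p ~ 1
  same <- compare_psi_by_frame(c(0.2, 0.4, 0.2, 0.4),
                               c("preserving", "preserving",
                                 "disrupting", "disrupting"))
  expect_gt(same$p_value, 0.9)
  # frozen 20-arrangement enumeration: most extreme split, two-sided 2/20
  extreme <- compare_psi_by_frame(
    c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1),
    c(rep("preserving", 3), rep("disrupting", 3))
  )
  expect_equal(extreme$p_value, 0.1)
  expect_equal(extreme$method, "exact permutation")
  # Bonferroni with one test leaves p unchanged; multiplier scales it
  expect_equal(extreme$p_adjusted, extreme$p_value)
  multi <- compare_psi_by_frame(
    c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1),
    c(rep("preserving", 3), rep("disrupting", 3)), n_tests = 5
  )
  expect_equal(multi$p_adjusted, 0.5)
  expect_error(compare_psi_by_frame(0.5, "preserving"), "one value per")
})

test_that("large samples agree with the normal-approximation test", {
  set.seed(303)
  x <- runif(60, 0.3, 0.9)
  y <- runif(60, 0.1, 0.6)
  fc <- c(rep("preserving", 60), rep("disrupting", 60))
  res <- compare_psi_by_frame(c(x, y), fc)
  expect_equal(res$method, "normal approximation")
  expect_equal(res$p_value, stats::wilcox.test(x, y, exact = FALSE)$p.value)
})
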