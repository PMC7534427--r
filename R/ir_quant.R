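# Percent intron retention (PIR) from read evidence at constitutive introns.
#
# For one intron and one sample, five quantities are counted from the
# MAPQ-filtered primary alignments:
#   sj           reads whose alignment gap excises the intron exactly
#   ie5 / ie3    ungapped reads crossing the exon-intron boundary at the
#                donor / acceptor splice site with >= min_anchor aligned
#                positions on both sides of the boundary
#   intron_reads reads with at least one aligned position inside the intron
#   intron_cov   mean per-base aligned depth over the intron
# After replicate averaging and the filter cascade,
#   PIR = (ie5 + ie3) / (ie5 + ie3 + sj).

#' Count intron-retention read evidence for one sample
#'
#' @param bam Path to a coordinate-sorted, indexed BAM (or SAM, converted
#'   transparently) file for one sample.
#' @param introns Tibble from [derive_introns()].
#' @param sample_id Sample label recorded in the output (defaults to the
#'   file name).
#' @param min_mapq Minimum mapping quality; lower-quality, unmapped,
#'   secondary and supplementary records are excluded from all counts.
#' @param min_anchor Minimum number of aligned reference positions required
#'   on both sides of a splice-site boundary for a boundary-crossing read to
#'   count toward `ie5`/`ie3`.
#' @return A tibble with one row per intron: `intron_id`, `sample_id`,
#'   `sj`, `ie5`, `ie3`, `intron_reads`, `intron_cov`.
#' @export
count_intron_evidence <- function(bam, introns, sample_id = basename(bam),
                                  min_mapq = 10, min_anchor = 10) {
  ga <- read_alignments(bam, min_mapq = min_mapq)
  check_chroms(ga, introns$chrom)

  intron_gr <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$start + 1L, introns$end)
  )
  segs <- read_segments(ga)
  flat_segs <- unlist(segs)
  gaps <- GenomicAlignments::junctions(ga)
  flat_gaps <- unlist(gaps)

  # sj: gap interval identical to the intron
  sj <- suppressWarnings(
    GenomicRanges::countOverlaps(intron_gr, flat_gaps, type = "equal")
  )

  # ie5/ie3: a contiguous aligned segment covering min_anchor positions on
  # both sides of the boundary. Genomic boundary of the 5' splice site is
  # the intron start on '+' and the intron end on '-'.
  boundary_window <- function(b) {
    # b is a 0-based boundary coordinate; window covers positions
    # [b - min_anchor, b + min_anchor) i.e. 1-based [b - min_anchor + 1, b + min_anchor]
    GenomicRanges::GRanges(
      introns$chrom,
      IRanges::IRanges(b - min_anchor + 1L, b + min_anchor)
    )
  }
  count_within <- function(win) {
    suppressWarnings(
      GenomicRanges::countOverlaps(win, flat_segs, type = "within")
    )
  }
  ie5 <- count_within(boundary_window(introns$donor))
  ie3 <- count_within(boundary_window(introns$acceptor))

  # reads with any aligned position inside the intron
  intron_reads <- suppressWarnings(
    GenomicRanges::countOverlaps(intron_gr, segs)
  )

  # mean per-base aligned depth over the intron
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intron_gr, flat_segs)
  )
  ov <- IRanges::pintersect(
    intron_gr[S4Vectors::queryHits(hits)],
    flat_segs[S4Vectors::subjectHits(hits)]
  )
  cov_bases <- rep(0, length(intron_gr))
  if (length(hits) > 0) {
    agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    cov_bases[as.integer(names(agg))] <- as.numeric(agg)
  }
  intron_cov <- cov_bases / (introns$end - introns$start)

  tibble::tibble(
    intron_id = introns$intron_id,
    sample_id = sample_id,
    sj = as.numeric(sj),
    ie5 = as.numeric(ie5),
    ie3 = as.numeric(ie3),
    intron_reads = as.numeric(intron_reads),
    intron_cov = intron_cov
  )
}

#' Average intron evidence counts across replicates
#'
#' Each count field (and the coverage) is averaged arithmetically across the
#' replicates of a timepoint, so averaged counts may be non-integer.
#'
#' @param counts Row-bound per-sample tibbles from [count_intron_evidence()].
#' @param design Sample sheet tibble with columns `sample_id`, `timepoint`,
#'   `replicate` (and optionally `phase`).
#' @return A tibble with one row per (intron, timepoint): `intron_id`,
#'   `timepoint`, `n_replicates`, and averaged `sj`, `ie5`, `ie3`,
#'   `intron_reads`, `intron_cov`.
#' @export
average_replicates <- function(counts, design) {
  stopifnot(all(c("sample_id", "timepoint") %in% names(design)))
  missing_tp <- setdiff(design$timepoint,
                        design$timepoint[design$sample_id %in%
                                           counts$sample_id])
  if (length(missing_tp) > 0) {
    stop("timepoint(s) with zero counted samples: ",
         paste(unique(missing_tp), collapse = ", "), call. = FALSE)
  }
  counts |>
    dplyr::inner_join(design[, c("sample_id", "timepoint")],
                      by = "sample_id") |>
    dplyr::group_by(.data$intron_id, .data$timepoint) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(c("sj", "ie5", "ie3", "intron_reads", "intron_cov"),
                    mean),
      .groups = "drop"
    )
}

#' Compute PIR from averaged intron counts with the filter cascade
#'
#' An intron-timepoint is `quantified` when `sj >= min_sj`, both boundary
#' counts reach `min_ie`, `intron_cov >= min_cov` and
#' `intron_reads >= min_intron_reads`; then
#' `PIR = (ie5 + ie3) / (ie5 + ie3 + sj)`. With `sj >= min_sj` but no
#' boundary-crossing reads at all (`ie5 + ie3 == 0`) the intron is fully
#' spliced at that timepoint: status `spliced_only`, PIR exactly 0. With
#' `sj < min_sj` there is insufficient evidence: status `insufficient`, PIR
#' `NA` by default or 0 when `insufficient_as_zero = TRUE`. Boundary
#' evidence that is present but below the filters also yields
#' `insufficient`.
#'
#' @param counts Tibble from [average_replicates()] (or
#'   [count_intron_evidence()] for a single sample; the grouping column is
#'   whatever the input carries).
#' @param min_sj,min_ie,min_cov,min_intron_reads Filter thresholds.
#' @param insufficient_as_zero Report insufficient cells as 0 instead of
#'   `NA` (compatibility mode).
#' @return The input with `pir` and `status` columns appended.
#' @export
compute_pir <- function(counts, min_sj = 5, min_ie = 2, min_cov = 1.0,
                        min_intron_reads = 5, insufficient_as_zero = FALSE) {
  num <- counts[, c("sj", "ie5", "ie3", "intron_reads", "intron_cov")]
  if (any(as.matrix(num) < 0, na.rm = TRUE)) {
    stop("negative counts are not allowed", call. = FALSE)
  }
  out <- counts |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$sj >= min_sj & (.data$ie5 + .data$ie3) == 0 ~ "spliced_only",
        .data$sj >= min_sj & .data$ie5 >= min_ie & .data$ie3 >= min_ie &
          .data$intron_cov >= min_cov &
          .data$intron_reads >= min_intron_reads ~ "quantified",
        TRUE ~ "insufficient"
      ),
      pir = dplyr::case_when(
        .data$status == "quantified" ~
          (.data$ie5 + .data$ie3) / (.data$ie5 + .data$ie3 + .data$sj),
        .data$status == "spliced_only" ~ 0,
        TRUE ~ NA_real_
      )
    )
  if (insufficient_as_zero) {
    out$pir[out$status == "insufficient"] <- 0
  }
  out
}

#' Build the introns-by-timepoints PIR matrix
#'
#' Rows are introns with maximal PIR across timepoints of at least
#' `min_pir`; a pseudo-count is added to every non-missing cell;
#' `insufficient` cells stay `NA`.
#'
#' @param quants Tibble from [compute_pir()] covering all
#'   (intron, timepoint) pairs.
#' @param design Sample sheet; its `timepoint` order (first appearance)
#'   fixes the column order.
#' @param min_pir Minimum of the per-row maximum PIR (pre-pseudo-count) for
#'   the intron to be retained.
#' @param pseudo Pseudo-count added to non-missing cells.
#' @return A wide tibble: `intron_id` plus one column per timepoint, with
#'   attributes `metric = "PIR"` and `pseudo`.
#' @export
build_pir_matrix <- function(quants, design, min_pir = 0.05, pseudo = 0.001) {
  tp_order <- as.character(unique(design$timepoint))
  keep <- quants |>
    dplyr::group_by(.data$intron_id) |>
    dplyr::summarise(max_pir = suppressWarnings(max(.data$pir, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::filter(is.finite(.data$max_pir), .data$max_pir >= min_pir)
  wide <- quants |>
    dplyr::semi_join(keep, by = "intron_id") |>
    dplyr::mutate(timepoint = as.character(.data$timepoint),
                  value = ifelse(is.na(.data$pir), NA_real_,
                                 .data$pir + pseudo)) |>
    dplyr::select("intron_id", "timepoint", "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
  wide <- wide[, c("intron_id", intersect(tp_order, names(wide)))]
  new_splicing_matrix(wide, metric = "PIR", pseudo = pseudo)
}
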