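# Splice-junction extraction and proportion-based PSI quantification.
#
# A junction is the genomic interval skipped by an alignment gap. Junctions
# of one gene sharing a boundary coordinate form a local splicing event;
# within an event each junction's PSI in a sample is its share of the
# event's reads. The junction with the highest mean PSI is canonical, the
# rest are alternates.

#' Extract splice junctions from one sample's alignments
#'
#' Every alignment gap whose two flanking aligned segments are each at
#' least `min_overhang` reference positions long contributes one read count
#' to the junction keyed by the gap interval. Gaps shorter than
#' `min_intron_len` or longer than `max_intron_len` are discarded.
#'
#' @param bam Path to an indexed BAM (or SAM) file.
#' @param sample_id Sample label recorded in the output.
#' @param min_overhang Minimum aligned length on both sides of the gap.
#' @param min_mapq Minimum mapping quality (0: no filter beyond dropping
#'   unmapped/secondary/supplementary records).
#' @param min_intron_len,max_intron_len Admissible gap lengths.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open gap interval),
#'   `sample_id`, `count`.
#' @export
extract_junctions <- function(bam, sample_id = basename(bam),
                              min_overhang = 8, min_mapq = 0,
                              min_intron_len = 10, max_intron_len = 3000) {
  ga <- read_alignments(bam, min_mapq = min_mapq)
  ga <- ga[GenomicAlignments::njunc(ga) > 0]
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), sample_id = character(),
                          count = integer())
  if (length(ga) == 0) return(empty)

  segs <- read_segments(ga)
  gaps <- GenomicAlignments::junctions(ga)
  nseg <- S4Vectors::elementNROWS(segs)
  ngap <- S4Vectors::elementNROWS(gaps)
  stopifnot(all(nseg == ngap + 1L))
  flat_segs <- unlist(segs)
  flat_gaps <- unlist(gaps)

  seg_off <- cumsum(nseg) - nseg            # per-read offset into flat_segs
  read_of_gap <- rep(seq_along(ga), ngap)
  gap_rank <- unlist(lapply(ngap, seq_len))
  left_idx <- seg_off[read_of_gap] + gap_rank
  right_idx <- left_idx + 1L

  w <- GenomicRanges::width(flat_gaps)
  ok <- GenomicRanges::width(flat_segs)[left_idx] >= min_overhang &
    GenomicRanges::width(flat_segs)[right_idx] >= min_overhang &
    w >= min_intron_len & w <= max_intron_len
  if (!any(ok)) return(empty)

  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(flat_gaps))[ok],
    start = GenomicRanges::start(flat_gaps)[ok] - 1L,
    end = GenomicRanges::end(flat_gaps)[ok]
  ) |>
    dplyr::count(.data$chrom, .data$start, .data$end, name = "count") |>
    dplyr::mutate(sample_id = sample_id, .before = "count")
}

#' Filter junctions for reproducibility, support and repeat overlap
#'
#' A junction survives iff (a) there is at least one timepoint at which
#' every replicate observed it, (b) its maximum per-sample read count
#' reaches `min_reads`, and (c) neither splice-site boundary base falls
#' inside a repeat interval.
#'
#' @param junctions Row-bound per-sample tibbles from
#'   [extract_junctions()].
#' @param design Sample sheet with `sample_id`, `timepoint`, `replicate`.
#' @param repeats Optional tibble from [load_repeats()]; `NULL` skips the
#'   repeat filter.
#' @param min_reads Minimum supporting reads in at least one sample.
#' @return The surviving junction rows (all samples).
#' @export
filter_junctions <- function(junctions, design, repeats = NULL,
                             min_reads = 2) {
  if (!"replicate" %in% names(design)) {
    stop("design must contain a 'replicate' column", call. = FALSE)
  }
  n_reps <- design |>
    dplyr::count(.data$timepoint, name = "n_expected")
  with_tp <- junctions |>
    dplyr::inner_join(design[, c("sample_id", "timepoint")],
                      by = "sample_id")
  in_all_reps <- with_tp |>
    dplyr::filter(.data$count >= 1) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$timepoint,
                    .data$sample_id) |>
    dplyr::count(.data$chrom, .data$start, .data$end, .data$timepoint,
                 name = "n_seen") |>
    dplyr::inner_join(n_reps, by = "timepoint") |>
    dplyr::filter(.data$n_seen == .data$n_expected) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end)
  supported <- junctions |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(max_count = max(.data$count), .groups = "drop") |>
    dplyr::filter(.data$max_count >= min_reads) |>
    dplyr::select(-"max_count")
  keep <- dplyr::inner_join(in_all_reps, supported,
                            by = c("chrom", "start", "end"))
  if (!is.null(repeats) && nrow(keep) > 0) {
    # boundary bases: first and last intronic base of the gap
    bad <- in_repeat(repeats, keep$chrom, keep$start) |
      in_repeat(repeats, keep$chrom, keep$end - 1L)
    keep <- keep[!bad, ]
  }
  dplyr::semi_join(junctions, keep, by = c("chrom", "start", "end"))
}

#' Group junctions into local splicing events
#'
#' Junctions of one gene sharing their genomic start form one event, and
#' junctions sharing their genomic end form another; a junction can belong
#' to one event per end. Events with a single junction are dropped.
#' Junctions not contained in any gene span are dropped with a message.
#'
#' @param junctions Filtered junction tibble (sample column ignored here).
#' @param gene_models Tibble from [load_annotation()].
#' @return Tibble with one row per (event, junction): `event_id`,
#'   `gene_id`, `chrom`, `strand`, `anchor_side` (`"left"`/`"right"`, the
#'   shared genomic end), `anchor` (its coordinate), `junction_id`
#'   (`chrom:start-end`), `start`, `end`.
#' @export
group_events <- function(junctions, gene_models) {
  uniq <- junctions |>
    dplyr::distinct(.data$chrom, .data$start, .data$end)
  gene_gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end)
  )
  jx_gr <- GenomicRanges::GRanges(
    uniq$chrom, IRanges::IRanges(uniq$start + 1L, uniq$end)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(jx_gr, gene_gr, type = "within")
  )
  first_hit <- !duplicated(S4Vectors::queryHits(hits))
  n_orphan <- nrow(uniq) -
    length(unique(S4Vectors::queryHits(hits)))
  if (n_orphan > 0) {
    message(n_orphan, " junction(s) not contained in any gene were dropped")
  }
  assigned <- uniq[S4Vectors::queryHits(hits)[first_hit], ]
  assigned$gene_id <- gene_models$gene_id[S4Vectors::subjectHits(hits)[first_hit]]
  assigned$strand <- gene_models$strand[S4Vectors::subjectHits(hits)[first_hit]]
  assigned$junction_id <- paste0(assigned$chrom, ":", assigned$start, "-",
                                 assigned$end)

  by_side <- function(side) {
    anchor <- if (side == "left") assigned$start else assigned$end
    assigned |>
      dplyr::mutate(anchor_side = side, anchor = anchor,
                    event_id = paste0(.data$gene_id, ":",
                                      ifelse(side == "left", "L", "R"),
                                      anchor)) |>
      dplyr::group_by(.data$event_id) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::ungroup()
  }
  dplyr::bind_rows(by_side("left"), by_side("right")) |>
    dplyr::select("event_id", "gene_id", "chrom", "strand", "anchor_side",
                  "anchor", "junction_id", "start", "end") |>
    dplyr::arrange(.data$event_id, .data$start, .data$end)
}

#' Compute per-junction PSI within events
#'
#' PSI of a junction in a sample is its read count divided by the total
#' reads of the event's junctions in that sample. Samples with zero event
#' reads get `NA` for every junction of the event.
#'
#' @param events Tibble from [group_events()].
#' @param junctions Per-sample junction counts (same universe the events
#'   were built from).
#' @param design Sample sheet; defines the full sample set so junctions
#'   unobserved in a sample count as zero.
#' @return Long tibble: `event_id`, `junction_id`, `gene_id`, `chrom`,
#'   `strand`, `anchor_side`, `anchor`, `start`, `end`, `sample_id`,
#'   `count`, `psi`.
#' @export
compute_psi <- function(events, junctions, design) {
  samples <- unique(design$sample_id)
  grid <- tidyr::crossing(events, sample_id = samples) |>
    dplyr::left_join(
      junctions |>
        dplyr::select("chrom", "start", "end", "sample_id", "count"),
      by = c("chrom", "start", "end", "sample_id")
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
  grid |>
    dplyr::group_by(.data$event_id, .data$sample_id) |>
    dplyr::mutate(
      total = sum(.data$count),
      psi = dplyr::if_else(.data$total > 0,
                           .data$count / .data$total, NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"total")
}

#' Annotate canonical and alternate junction roles
#'
#' Within each event the junction with the highest mean PSI across samples
#' with data is canonical; every other junction is an alternate. Ties are
#' broken deterministically by lower genomic start, then lower end.
#'
#' @param psi Long tibble from [compute_psi()].
#' @return The input with `mean_psi` and `role` columns.
#' @export
annotate_roles <- function(psi) {
  means <- psi |>
    dplyr::group_by(.data$event_id, .data$junction_id, .data$start,
                    .data$end) |>
    dplyr::summarise(mean_psi = mean(.data$psi, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$event_id, dplyr::desc(.data$mean_psi),
                   .data$start, .data$end) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::mutate(role = c("canonical",
                           rep("alternate", dplyr::n() - 1L))) |>
    dplyr::ungroup() |>
    dplyr::select("event_id", "junction_id", "mean_psi", "role")
  dplyr::left_join(psi, means, by = c("event_id", "junction_id"))
}

#' Drop noisy events
#'
#' An event is retained iff some alternate junction reaches a PSI above
#' `min_alt_psi` in at least one sample, and some alternate junction is
#' supported by at least `min_alt_reads` reads in at least one sample.
#'
#' @param psi Role-annotated long tibble from [annotate_roles()].
#' @param min_alt_psi PSI that at least one alternate must exceed.
#' @param min_alt_reads Read count at least one alternate must reach.
#' @return The retained events' rows.
#' @export
filter_events <- function(psi, min_alt_psi = 0.05, min_alt_reads = 2) {
  keep <- psi |>
    dplyr::filter(.data$role == "alternate") |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      psi_ok = any(.data$psi > min_alt_psi, na.rm = TRUE),
      reads_ok = any(.data$count >= min_alt_reads),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$psi_ok, .data$reads_ok)
  dplyr::semi_join(psi, keep, by = "event_id")
}

#' Build the alternate-junctions-by-timepoints PSI matrix
#'
#' Rows are the alternate junctions of the retained events; each cell is
#' the mean PSI over the timepoint's replicates with data; cells with no
#' data at all are set to the pseudo-count.
#'
#' @param psi Filtered, role-annotated long tibble.
#' @param design Sample sheet (fixes timepoint column order).
#' @param pseudo Value replacing null cells.
#' @return Wide tibble: `row_id` (`event_id|junction_id`) plus one column
#'   per timepoint, attributes `metric = "PSI"` and `pseudo`.
#' @export
build_psi_matrix <- function(psi, design, pseudo = 0.0001) {
  tp_order <- as.character(unique(design$timepoint))
  long <- psi |>
    dplyr::filter(.data$role == "alternate") |>
    dplyr::inner_join(design[, c("sample_id", "timepoint")],
                      by = "sample_id") |>
    dplyr::group_by(.data$event_id, .data$junction_id, .data$timepoint) |>
    dplyr::summarise(
      value = if (all(is.na(.data$psi))) pseudo else
        mean(.data$psi, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      row_id = paste0(.data$event_id, "|", .data$junction_id),
      timepoint = as.character(.data$timepoint)
    )
  wide <- long |>
    dplyr::select("row_id", "timepoint", "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value",
                       values_fill = pseudo)
  wide <- wide[, c("row_id", intersect(tp_order, names(wide)))]
  new_splicing_matrix(wide, metric = "PSI", pseudo = pseudo)
}
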