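# Gene-model derivation: merged exons and the constitutive introns between
# them. All coordinates inside the package are 0-based half-open; GFF3 is
# converted from 1-based inclusive on input, BED is taken as-is.

#' Load gene models from a GFF3 annotation
#'
#' Reads gene and exon features from a GFF3 file, pools the exons of all
#' transcripts of each gene, and merges overlapping (and touching) exon
#' intervals. The gaps between consecutive merged exons are the gene's
#' constitutive introns, obtainable with [derive_introns()].
#'
#' @param gff3_path Path to a GFF3 file with `gene` and `exon` features.
#'   Exons must be attributable to a gene either directly (a `Parent` or
#'   `gene_id` pointing at a gene) or through their transcript's `Parent`.
#' @return A tibble with one row per gene and columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (gene span, 0-based half-open), `n_exons`
#'   (number of merged exons) and a list-column `exons` of tibbles with
#'   `start`/`end` of each merged exon, sorted by start.
#'   Exons whose gene parent cannot be resolved are skipped with a warning
#'   giving the count.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
#'   "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=t1"), gff)
#' genes <- load_annotation(gff)
#' derive_introns(genes)
#' @export
load_annotation <- function(gff3_path) {
  gr <- tryCatch(
    rtracklayer::import(gff3_path, format = "gff3"),
    error = function(e) {
      stop("failed to parse GFF3 '", gff3_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else
    rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  gene_ids <- ids[is_gene]
  # feature ID -> owning gene, following one level of Parent (mRNA/transcript)
  parent_of <- function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }
  tx_to_gene <- list()
  is_tx <- !is_gene & type != "exon"
  for (i in which(is_tx)) {
    if (!is.na(ids[i])) tx_to_gene[[ids[i]]] <- parent_of(i)
  }

  exon_idx <- which(type == "exon")
  exon_gene <- character(length(exon_idx))
  for (k in seq_along(exon_idx)) {
    i <- exon_idx[k]
    p <- parent_of(i)
    g <- if (!is.na(p) && p %in% gene_ids) p
         else if (!is.na(p) && !is.null(tx_to_gene[[p]])) tx_to_gene[[p]]
         else NA_character_
    exon_gene[k] <- if (!is.na(g) && g %in% gene_ids) g else NA_character_
  }
  n_orphan <- sum(is.na(exon_gene))
  if (n_orphan > 0) {
    warning(n_orphan, " exon(s) without a resolvable gene parent were skipped")
  }
  keep <- !is.na(exon_gene)
  exon_idx <- exon_idx[keep]
  exon_gene <- exon_gene[keep]

  exons <- tibble::tibble(
    gene_id = exon_gene,
    chrom = as.character(GenomicRanges::seqnames(gr))[exon_idx],
    strand = as.character(GenomicRanges::strand(gr))[exon_idx],
    start = GenomicRanges::start(gr)[exon_idx] - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr)[exon_idx]
  )

  exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      exons = list(merge_exons(data.frame(start = start, end = end))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      start = purrr::map_int(.data$exons, ~ as.integer(min(.x$start))),
      end = purrr::map_int(.data$exons, ~ as.integer(max(.x$end))),
      n_exons = purrr::map_int(.data$exons, nrow)
    ) |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end",
                  "n_exons", "exons") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Merge overlapping or touching intervals
#'
#' Intervals are 0-based half-open. Touching intervals (one's `end` equal to
#' the next's `start`) are merged, so no zero-length gap can survive.
#'
#' @param intervals A data frame with integer columns `start` and `end`
#'   (`start < end` for every row).
#' @return A tibble of disjoint, non-adjacent intervals sorted by `start`,
#'   whose union equals the union of the input.
#' @export
merge_exons <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    stop("merge_exons() needs at least one interval")
  }
  if (any(intervals$start >= intervals$end)) {
    stop("every interval must have start < end")
  }
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir)  # default min.gapwidth = 1 also merges touching
  tibble::tibble(
    start = IRanges::start(red) - 1L,
    end = IRanges::end(red)
  )
}

#' Derive constitutive introns from merged gene models
#'
#' The constitutive introns of a gene are exactly the gaps between its
#' consecutive merged exons. Introns are numbered in transcription order
#' (left to right on `+`, right to left on `-`). The donor splice site is
#' the boundary at the intron's 5' end in transcription order (its lower
#' coordinate on `+`, its upper coordinate on `-`); the acceptor is the
#' opposite boundary.
#'
#' @param gene_models A tibble from [load_annotation()].
#' @return A tibble with one row per intron: `intron_id` (`gene_id:rank`),
#'   `gene_id`, `chrom`, `strand`, `start`, `end` (0-based half-open),
#'   `intron_rank`, `donor`, `acceptor` (boundary coordinates), and
#'   `overlaps_gene_exon`, flagging introns that overlap a merged exon of a
#'   *different* gene (they are retained; the flag preserves the information).
#' @export
derive_introns <- function(gene_models) {
  per_gene <- purrr::pmap(
    list(gene_models$gene_id, gene_models$chrom, gene_models$strand,
         gene_models$exons),
    function(gene_id, chrom, strand, exons) {
      n <- nrow(exons)
      if (n < 2) return(NULL)
      istart <- exons$end[-n]
      iend <- exons$start[-1]
      minus <- strand == "-"
      rank <- if (minus) rev(seq_len(n - 1L)) else seq_len(n - 1L)
      tibble::tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = istart, end = iend, intron_rank = rank,
        donor = if (minus) iend else istart,
        acceptor = if (minus) istart else iend
      )
    }
  )
  introns <- dplyr::bind_rows(per_gene)
  if (nrow(introns) == 0) {
    return(tibble::tibble(
      intron_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      intron_rank = integer(), donor = integer(), acceptor = integer(),
      overlaps_gene_exon = logical()
    ))
  }
  introns <- introns |>
    dplyr::mutate(intron_id = paste0(.data$gene_id, ":", .data$intron_rank)) |>
    dplyr::select("intron_id", dplyr::everything())

  # flag introns overlapping another gene's merged exons
  all_exons <- gene_models |>
    dplyr::select("gene_id", "chrom", "exons") |>
    tidyr::unnest("exons")
  exon_gr <- GenomicRanges::GRanges(
    all_exons$chrom,
    IRanges::IRanges(all_exons$start + 1L, all_exons$end)
  )
  intron_gr <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$start + 1L, introns$end)
  )
  hits <- GenomicRanges::findOverlaps(intron_gr, exon_gr)
  other <- introns$gene_id[S4Vectors::queryHits(hits)] !=
    all_exons$gene_id[S4Vectors::subjectHits(hits)]
  flagged <- unique(S4Vectors::queryHits(hits)[other])
  introns$overlaps_gene_exon <- seq_len(nrow(introns)) %in% flagged
  introns
}

#' Load repeat-region intervals from a BED file
#'
#' @param bed_path Path to a BED3+ file (0-based half-open). Unsorted input
#'   is accepted and sorted internally.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted by
#'   chromosome and start, carrying an index used by [in_repeat()].
#' @export
load_repeats <- function(bed_path) {
  gr <- tryCatch(
    rtracklayer::import(bed_path, format = "bed"),
    error = function(e) {
      stop("failed to parse BED '", bed_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  gr <- GenomicRanges::sort(gr)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  attr(out, "granges") <- gr
  class(out) <- c("repeat_intervals", class(out))
  out
}

#' Query repeat-region overlap
#'
#' @param repeats A tibble from [load_repeats()].
#' @param chrom Chromosome name(s).
#' @param start Interval start(s), 0-based; for a point query give the point.
#' @param end Interval end(s), half-open; defaults to `start + 1` (point).
#' @return Logical vector: does each query overlap any repeat interval?
#' @export
in_repeat <- function(repeats, chrom, start, end = start + 1L) {
  gr <- attr(repeats, "granges")
  if (is.null(gr)) {
    gr <- GenomicRanges::GRanges(
      repeats$chrom, IRanges::IRanges(repeats$start + 1L, repeats$end)
    )
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  suppressWarnings(GenomicRanges::countOverlaps(q, gr) > 0)
}

#' Write derived introns to TSV
#'
#' @param introns Tibble from [derive_introns()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_introns_tsv <- function(introns, path) {
  readr::write_tsv(
    introns |>
      dplyr::select("intron_id", "chrom", "start", "end", "strand", "gene_id"),
    path
  )
  invisible(path)
}
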