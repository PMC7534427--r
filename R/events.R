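# Event-level consequences: event type, reading-frame class, six-frame
# premature-stop scan of inserted sequence, phase occurrence, and the
# frame-class PSI comparison.

#' Classify splicing events by type and reading-frame consequence
#'
#' Events with more than one significant alternate junction (PSI above
#' `sig_psi` in some sample) are `complex` and not given a frame class.
#' Otherwise the top alternate is compared to the canonical junction: if it
#' spans at least one entire merged exon that the canonical junction does
#' not span, the event is exon skipping (`ES`) and `delta_nt` is the total
#' skipped exon length; else the event varies at one end and is `Alt5` or
#' `Alt3` according to whether the varying boundary is the donor or the
#' acceptor on the gene's strand, with `delta_nt` the absolute coordinate
#' difference. Events without gene context are `unclassified`.
#'
#' Frame class is `preserving` iff `delta_nt` is divisible by 3. When the
#' alternate junction excises *less* than the canonical one, the extra
#' genomic interval retained by the alternate form is reported as
#' `inserted_start`/`inserted_end`, and for frame-preserving events the
#' inserted residue count `n_inserted_aa = delta_nt / 3`.
#'
#' @param psi Filtered, role-annotated long tibble
#'   (see [annotate_roles()], [filter_events()]).
#' @param gene_models Tibble from [load_annotation()].
#' @param sig_psi Significance threshold on per-sample PSI for counting
#'   alternates toward complexity.
#' @return One row per event: `event_id`, `gene_id`, `strand`,
#'   `event_type`, `canonical_id`, `alternate_id`, `delta_nt`,
#'   `frame_class`, `inserted_start`, `inserted_end`, `n_inserted_aa`.
#' @export
classify_events <- function(psi, gene_models, sig_psi = 0.05) {
  per_junction <- psi |>
    dplyr::group_by(.data$event_id, .data$gene_id, .data$chrom,
                    .data$strand, .data$anchor_side, .data$junction_id,
                    .data$start, .data$end, .data$role, .data$mean_psi) |>
    dplyr::summarise(max_psi = suppressWarnings(max(.data$psi, na.rm = TRUE)),
                     .groups = "drop")
  exon_sets <- stats::setNames(gene_models$exons, gene_models$gene_id)

  per_junction |>
    dplyr::group_by(.data$event_id) |>
    dplyr::group_modify(~ classify_one_event(.x, exon_sets, sig_psi)) |>
    dplyr::ungroup()
}

classify_one_event <- function(jx, exon_sets, sig_psi) {
  canon <- jx[jx$role == "canonical", ][1, ]
  alts <- jx[jx$role == "alternate", ]
  alts <- alts[order(-alts$mean_psi, alts$start, alts$end), ]
  n_sig <- sum(is.finite(alts$max_psi) & alts$max_psi > sig_psi)
  alt <- alts[1, ]
  base <- tibble::tibble(
    gene_id = canon$gene_id, chrom = canon$chrom, strand = canon$strand,
    canonical_id = canon$junction_id, alternate_id = alt$junction_id,
    event_type = NA_character_, delta_nt = NA_integer_,
    frame_class = NA_character_,
    inserted_start = NA_integer_, inserted_end = NA_integer_,
    n_inserted_aa = NA_integer_
  )
  if (n_sig > 1) {
    base$event_type <- "complex"
    base$frame_class <- "complex_excluded"
    return(base)
  }
  exons <- exon_sets[[canon$gene_id]]
  if (is.null(exons)) {
    base$event_type <- "unclassified"
    return(base)
  }
  spans <- function(j, ex) ex$start >= j$start & ex$end <= j$end
  skipped <- spans(alt, exons) & !spans(canon, exons)
  if (any(skipped)) {
    base$event_type <- "ES"
    base$delta_nt <- as.integer(sum(exons$end[skipped] -
                                      exons$start[skipped]))
  } else {
    varying_is_left <- canon$anchor_side == "right"
    # left genomic boundary is the donor on '+' and the acceptor on '-'
    base$event_type <- if (varying_is_left) {
      if (canon$strand == "-") "Alt3" else "Alt5"
    } else {
      if (canon$strand == "-") "Alt5" else "Alt3"
    }
    vc <- if (varying_is_left) canon$start else canon$end
    va <- if (varying_is_left) alt$start else alt$end
    base$delta_nt <- abs(va - vc)
    # alternate excises less than canonical -> extra sequence retained
    alt_shorter <- (alt$end - alt$start) < (canon$end - canon$start)
    if (alt_shorter) {
      base$inserted_start <- min(va, vc)
      base$inserted_end <- max(va, vc)
    }
  }
  base$frame_class <- frame_class(base$delta_nt)
  if (identical(base$frame_class, "preserving") &&
      !is.na(base$inserted_start)) {
    base$n_inserted_aa <- base$delta_nt %/% 3L
  }
  base
}

#' Reading-frame class of a length difference
#'
#' @param delta_nt Integer vector of nucleotide length differences between
#'   alternate and canonical forms (skipped-exon length for ES events).
#' @return `"preserving"` where `delta_nt` is divisible by 3, otherwise
#'   `"disrupting"`; `NA` propagates.
#' @export
frame_class <- function(delta_nt) {
  ifelse(is.na(delta_nt), NA_character_,
         ifelse(delta_nt %% 3 == 0, "preserving", "disrupting"))
}

#' Six-frame premature-stop scan of an inserted sequence
#'
#' Scans the three forward frames of the sequence and the three frames of
#' its reverse complement for any in-frame stop codon (TAA, TAG, TGA).
#' Codons containing `N` never count as stops.
#'
#' @param inserted_seq Character vector of nucleotide sequences over
#'   `A,C,G,T,N` (case-insensitive; empty strings allowed).
#' @return A tibble with one row per sequence: logical flags `f1`, `f2`,
#'   `f3` (forward frames), `r1`, `r2`, `r3` (reverse-complement frames)
#'   and `all_six`, true iff every frame contains a stop codon.
#' @export
scan_ptc <- function(inserted_seq) {
  seqs <- toupper(as.character(inserted_seq))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide character in sequence(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  stops <- c("TAA", "TAG", "TGA")
  frame_has_stop <- function(s, offset) {
    n <- nchar(s)
    if (n - offset < 3) return(FALSE)
    starts <- seq(offset + 1L, n - 2L, by = 3L)
    any(substring(s, starts, starts + 2L) %in% stops)
  }
  scan_one <- function(s) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))
    )
    fwd <- vapply(0:2, function(o) frame_has_stop(s, o), logical(1))
    rev <- vapply(0:2, function(o) frame_has_stop(rc, o), logical(1))
    c(fwd, rev)
  }
  flags <- t(vapply(seqs, scan_one, logical(6), USE.NAMES = FALSE))
  out <- tibble::as_tibble(as.data.frame(flags))
  names(out) <- c("f1", "f2", "f3", "r1", "r2", "r3")
  out$all_six <- rowSums(flags) == 6L
  out
}

#' Fetch the inserted genomic sequence of classified events
#'
#' @param consequences Tibble from [classify_events()] joined with the
#'   events' `chrom` (columns `chrom`, `inserted_start`, `inserted_end`).
#' @param fasta Path to the genome FASTA.
#' @return Character vector of inserted sequences (empty string where no
#'   insertion).
#' @export
inserted_sequence <- function(consequences, fasta) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  out <- character(nrow(consequences))
  has <- !is.na(consequences$inserted_start)
  for (i in which(has)) {
    out[i] <- as.character(Biostrings::subseq(
      genome[[consequences$chrom[i]]],
      consequences$inserted_start[i] + 1L,
      consequences$inserted_end[i]
    ))
  }
  out
}

#' Diurnal phase of numeric timepoints
#'
#' Timepoints 1-10 are Light G1, 11-15 (including the half-hour points)
#' are S-M, and 16-24 are Dark G1.
#'
#' @param timepoint Numeric vector of hours from onset of illumination.
#' @return Character vector in `{"LightG1", "SM", "DarkG1"}`.
#' @export
diurnal_phases <- function(timepoint) {
  dplyr::case_when(
    timepoint <= 10 ~ "LightG1",
    timepoint <= 15 ~ "SM",
    TRUE ~ "DarkG1"
  )
}

#' Phase occurrence of matrix rows
#'
#' A row occurs in a phase iff its value exceeds `threshold` at one or more
#' timepoints of that phase. The default threshold is the matrix's
#' pseudo-count, so pseudo-filled cells denote absence.
#'
#' @param mat Wide matrix tibble ([build_psi_matrix()],
#'   [build_pir_matrix()]).
#' @param phase_design Tibble mapping `timepoint` to `phase`.
#' @param threshold Strict lower bound for presence.
#' @return Tibble: `row_id`, one logical column per phase, and `phases`, a
#'   list-column with the occurrence set of each row.
#' @export
phase_occurrence <- function(mat, phase_design,
                             threshold = attr(mat, "pseudo")) {
  if (is.null(threshold)) threshold <- 0
  m <- matrix_values(mat)
  phases <- unique(phase_design$phase)
  out <- tibble::tibble(row_id = rownames(m))
  for (p in phases) {
    tps <- as.character(
      phase_design$timepoint[phase_design$phase == p]
    )
    tps <- intersect(tps, colnames(m))
    vals <- m[, tps, drop = FALSE]
    out[[p]] <- apply(vals, 1, function(v) any(v > threshold, na.rm = TRUE))
  }
  out$phases <- apply(as.matrix(out[, phases, drop = FALSE]), 1,
                      function(z) phases[z], simplify = FALSE)
  out
}

#' Compare PSI between frame-preserving and frame-disrupting events
#'
#' Two-sided Wilcoxon rank-sum test on per-junction mean PSI between the
#' two frame classes. For small samples the exact permutation distribution
#' of the rank sum is enumerated (R's `wilcox.test` has no exact treatment
#' of ties); larger samples use the normal approximation. The Bonferroni
#' multiplier is the number of tests run in the batch.
#'
#' @param mean_psi Numeric vector of per-junction mean PSI values.
#' @param frame_class Character vector, `"preserving"`/`"disrupting"`,
#'   parallel to `mean_psi` (other values are dropped).
#' @param n_tests Bonferroni multiplier.
#' @param alpha Significance level on the corrected p-value.
#' @return One-row tibble: `statistic` (rank-sum W of the preserving
#'   class), `p_value`, `p_adjusted`, `significant`, `n_preserving`,
#'   `n_disrupting`, `method`.
#' @export
compare_psi_by_frame <- function(mean_psi, frame_class, n_tests = 1,
                                 alpha = 0.01) {
  keep <- frame_class %in% c("preserving", "disrupting") & !is.na(mean_psi)
  x <- mean_psi[keep & frame_class == "preserving"]
  y <- mean_psi[keep & frame_class == "disrupting"]
  if (length(x) < 1 || length(y) < 1) {
    stop("need at least one value per frame class", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (choose(n, n1) <= 2e5) {
    mu <- n1 * (n + 1) / 2
    sums <- utils::combn(n, n1, function(i) sum(r[i]))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    method <- "normal approximation"
  }
  p_adj <- min(1, p * n_tests)
  tibble::tibble(
    statistic = w, p_value = p, p_adjusted = p_adj,
    significant = p_adj < alpha,
    n_preserving = n1, n_disrupting = n2, method = method
  )
}

#' Write event consequences to TSV
#'
#' @param consequences Tibble from [classify_events()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_consequences_tsv <- function(consequences, path) {
  readr::write_tsv(consequences, path, na = "NA")
  invisible(path)
}
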