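# Test helpers: hand-built SAM fixtures and independent per-read oracle
# classifiers. The oracle walks CIGAR strings with plain string/loop
# arithmetic and classifies reads by explicit position tests; it shares no
# code path with the package's GenomicAlignments-based counters.

make_read <- function(qname, pos0, cigar, mapq = 60, flag = 0) {
  tibble::tibble(qname = qname, flag = flag, pos0 = pos0, mapq = mapq,
                 cigar = cigar)
}

# write reads (0-based pos0) to an indexed BAM; returns the BAM path
write_reads_bam <- function(reads, chrom = "chr1", chrom_len = 10000,
                            dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- reads[order(reads$pos0), ]
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
            reads$qname, reads$flag, chrom, reads$pos0 + 1L, reads$mapq,
            reads$cigar)
  )
  sam <- file.path(dir, "reads.sam")
  writeLines(lines, sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# walk a CIGAR: maximal aligned reference runs (0-based half-open) and the
# N-gap intervals, by plain string arithmetic
cigar_walk <- function(pos0, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- substring(ops, nchar(ops), nchar(ops))
  cur <- pos0
  runs <- list(); gaps <- list()
  run_start <- NA_integer_
  for (k in seq_along(ops)) {
    if (kinds[k] %in% c("M", "=", "X")) {
      if (is.na(run_start)) run_start <- cur
      cur <- cur + lens[k]
    } else if (kinds[k] == "N") {
      if (!is.na(run_start)) {
        runs[[length(runs) + 1L]] <- c(run_start, cur)
        run_start <- NA_integer_
      }
      gaps[[length(gaps) + 1L]] <- c(cur, cur + lens[k])
      cur <- cur + lens[k]
    } else if (kinds[k] == "D") {
      cur <- cur + lens[k]   # consumes reference, not aligned
      if (!is.na(run_start)) {
        runs[[length(runs) + 1L]] <- c(run_start, cur - lens[k])
        run_start <- NA_integer_
      }
    }
    # I/S/H/P do not consume reference
  }
  if (!is.na(run_start)) runs[[length(runs) + 1L]] <- c(run_start, cur)
  list(runs = runs, gaps = gaps)
}

oracle_keep_read <- function(flag, mapq, min_mapq) {
  !bitwAnd(flag, 4L) && !bitwAnd(flag, 256L) && !bitwAnd(flag, 2048L) &&
    mapq >= min_mapq
}

# naive per-read classification of the five intron evidence counts
oracle_intron_counts <- function(reads, intron_start, intron_end, donor,
                                 acceptor, min_mapq = 10, min_anchor = 10) {
  sj <- 0; ie5 <- 0; ie3 <- 0; nin <- 0; covered <- 0
  boundary_ok <- function(runs, b) {
    for (r in runs) {
      if (r[1] <= b - min_anchor && r[2] >= b + min_anchor) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(nrow(reads))) {
    if (!oracle_keep_read(reads$flag[i], reads$mapq[i], min_mapq)) next
    w <- cigar_walk(reads$pos0[i], reads$cigar[i])
    for (g in w$gaps) {
      if (g[1] == intron_start && g[2] == intron_end) sj <- sj + 1
    }
    if (boundary_ok(w$runs, donor)) ie5 <- ie5 + 1
    if (boundary_ok(w$runs, acceptor)) ie3 <- ie3 + 1
    ov <- 0
    for (r in w$runs) {
      ov <- ov + max(0, min(r[2], intron_end) - max(r[1], intron_start))
    }
    if (ov > 0) nin <- nin + 1
    covered <- covered + ov
  }
  list(sj = sj, ie5 = ie5, ie3 = ie3, intron_reads = nin,
       intron_cov = covered / (intron_end - intron_start))
}

# naive junction extraction: every N gap with both flanking aligned runs
# >= min_overhang and length within bounds
oracle_junctions <- function(reads, min_overhang = 8, min_mapq = 0,
                             min_len = 10, max_len = 3000) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    if (!oracle_keep_read(reads$flag[i], reads$mapq[i], min_mapq)) next
    w <- cigar_walk(reads$pos0[i], reads$cigar[i])
    for (k in seq_along(w$gaps)) {
      g <- w$gaps[[k]]
      left <- w$runs[[k]]; right <- w$runs[[k + 1L]]
      len <- g[2] - g[1]
      if (left[2] - left[1] >= min_overhang &&
          right[2] - right[1] >= min_overhang &&
          len >= min_len && len <= max_len) {
        out[[length(out) + 1L]] <- c(g[1], g[2])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          count = integer()))
  }
  do.call(rbind, out) |>
    as.data.frame() |>
    stats::setNames(c("start", "end")) |>
    dplyr::count(start, end, name = "count") |>
    tibble::as_tibble()
}

# independent six-frame stop check through Biostrings translation
oracle_all_six_stops <- function(s) {
  d <- Biostrings::DNAString(s)
  rc <- Biostrings::reverseComplement(d)
  has_stop <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3
    if (n < 3) return(FALSE)
    aa <- suppressWarnings(
      Biostrings::translate(Biostrings::subseq(x, off + 1L, off + n))
    )
    grepl("\\*", as.character(aa))
  }
  all(vapply(0:2, function(o) has_stop(d, o), logical(1))) &&
    all(vapply(0:2, function(o) has_stop(rc, o), logical(1)))
}

# random gapped/ungapped reads over a toy chromosome, with decoy low-MAPQ,
# secondary and supplementary records
random_reads <- function(n, pos_range = 600, read_len = 50) {
  pos <- sample.int(pos_range, n, replace = TRUE) - 1L
  cigar <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < 0.5) {
      cigar[i] <- paste0(read_len, "M")
    } else {
      left <- sample(1:(read_len - 1L), 1)
      gap <- sample(c(5L, 50L, 100L, 200L, 500L), 1)  # some below min length
      cigar[i] <- paste0(left, "M", gap, "N", read_len - left, "M")
    }
  }
  mapq <- sample(c(0L, 5L, 10L, 60L), n, replace = TRUE,
                 prob = c(0.1, 0.1, 0.2, 0.6))
  flag <- sample(c(0L, 256L, 2048L), n, replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
  make_read(sprintf("r%04d", seq_len(n)), pos, cigar, mapq, flag)
}

# small standard design: two replicates per timepoint
toy_design <- function(timepoints = c("TP1", "TP2")) {
  tidyr::expand_grid(timepoint = timepoints, replicate = 1:2) |>
    dplyr::mutate(sample_id = paste0(timepoint, "_R", replicate)) |>
    dplyr::select(sample_id, timepoint, replicate)
}
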