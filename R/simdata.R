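# Synthetic spliced-read simulator. A toy genome carries two gene shapes:
# "ir" genes (exon-intron-exon) whose fragments come from the
# intron-retained isoform with a per-timepoint probability r(t), and "psi"
# genes (two alternative acceptors for one donor) whose fragments come from
# the shorter-intron alternate isoform with probability p(t). Reads are
# placed uniformly along the chosen isoform, so the expected observed PIR
# and PSI have closed forms recorded in the truth table.

#' Describe a synthetic splicing time-course dataset
#'
#' Defaults mirror a diurnal cell-cycle design: timepoints 1-24 hours with
#' half-hour points between 11 and 15, two replicates per timepoint, and
#' phases Light G1 (1-10), S-M (11-15), Dark G1 (16-24). Default
#' trajectories alternate two archetypes per gene type: dark-high
#' (low in the light hours, high in the dark) and flat.
#'
#' @param n_ir_genes,n_psi_genes Number of intron-retention and
#'   alternative-acceptor genes.
#' @param timepoints Numeric hours from onset of illumination.
#' @param replicates Replicates per timepoint.
#' @param read_length Read length (nt, single-end).
#' @param depth Reads per gene per sample.
#' @param exon_length,intron_length Exon and (canonical) intron sizes (nt);
#'   intron length must lie in `[10, 3000]`.
#' @param alt_offsets Per-psi-gene distance (nt) between the canonical and
#'   alternate acceptor; recycled. The default mixes frame-preserving and
#'   frame-disrupting offsets.
#' @param frac_low_mapq Fraction of decoy reads emitted with MAPQ 0 (all
#'   other reads have MAPQ 60).
#' @param ir_trajectories,psi_trajectories Optional numeric matrices
#'   (genes x timepoints) of truth values in `[0, 1]`; defaults build the
#'   two archetypes.
#' @param stopfree_insertion Fill the alternate-retained interval of psi
#'   genes with a sequence free of stop codons in all six frames.
#' @param seed RNG seed; every output is reproducible from it.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_ir_genes = 5, n_psi_genes = 5,
                       timepoints = c(1:11, seq(11.5, 15, by = 0.5), 16:24),
                       replicates = 2, read_length = 100, depth = 300,
                       exon_length = 300, intron_length = 250,
                       alt_offsets = c(177, 50, 91), frac_low_mapq = 0.1,
                       ir_trajectories = NULL, psi_trajectories = NULL,
                       stopfree_insertion = FALSE, seed = 42) {
  stopifnot(intron_length >= 10, intron_length <= 3000,
            read_length < 2 * exon_length + intron_length,
            depth >= 1)
  n_tp <- length(timepoints)
  archetype <- function(kind) {
    switch(kind,
      dark_high = ifelse(timepoints > 12, 0.6, 0.05),
      flat = rep(0.3, n_tp),
      psi_dark_high = ifelse(timepoints > 12, 0.8, 0.1),
      psi_flat = rep(0.5, n_tp)
    )
  }
  if (is.null(ir_trajectories) && n_ir_genes > 0) {
    kinds <- rep(c("dark_high", "flat"), length.out = n_ir_genes)
    ir_trajectories <- do.call(rbind, lapply(kinds, archetype))
  }
  if (is.null(psi_trajectories) && n_psi_genes > 0) {
    kinds <- rep(c("psi_dark_high", "psi_flat"), length.out = n_psi_genes)
    psi_trajectories <- do.call(rbind, lapply(kinds, archetype))
  }
  check_traj <- function(m, n) {
    if (n == 0) return(invisible())
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == n_tp,
              all(m >= 0 & m <= 1))
  }
  check_traj(ir_trajectories, n_ir_genes)
  check_traj(psi_trajectories, n_psi_genes)
  if (n_psi_genes > 0) {
    alt_offsets <- rep(alt_offsets, length.out = n_psi_genes)
    stopifnot(all(intron_length - alt_offsets >= 10))
  }
  structure(list(
    n_ir_genes = n_ir_genes, n_psi_genes = n_psi_genes,
    timepoints = timepoints, replicates = replicates,
    read_length = read_length, depth = depth,
    exon_length = exon_length, intron_length = intron_length,
    alt_offsets = alt_offsets, frac_low_mapq = frac_low_mapq,
    ir_trajectories = ir_trajectories, psi_trajectories = psi_trajectories,
    stopfree_insertion = stopfree_insertion, seed = seed
  ), class = "sim_design")
}

#' Sample sheet of a simulation design
#'
#' @param design A `sim_design` object.
#' @return Tibble: `sample_id`, `timepoint` (label `TP<hours>`), `hours`,
#'   `replicate`, `phase`.
#' @export
sim_samples <- function(design) {
  tidyr::crossing(hours = design$timepoints,
                  replicate = seq_len(design$replicates)) |>
    dplyr::mutate(
      timepoint = paste0("TP", .data$hours),
      sample_id = paste0(.data$timepoint, "_R", .data$replicate),
      phase = diurnal_phases(.data$hours)
    ) |>
    dplyr::arrange(match(.data$hours, design$timepoints),
                   .data$replicate) |>
    dplyr::select("sample_id", "timepoint", "hours", "replicate", "phase")
}

# gene layout table: genomic coordinates (0-based half-open) of each gene
sim_gene_layout <- function(design) {
  E <- design$exon_length; I <- design$intron_length
  spacer <- 500L
  n <- design$n_ir_genes + design$n_psi_genes
  types <- c(rep("ir", design$n_ir_genes),
             rep("psi", design$n_psi_genes))
  gene_len <- 2L * E + I
  gstart <- spacer + (seq_len(n) - 1L) * (gene_len + spacer)
  layout <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    type = types,
    strand = rep(c("+", "-"), length.out = n),
    chrom = "chrS",
    gstart = as.integer(gstart),
    gend = as.integer(gstart + gene_len),
    e1_end = as.integer(gstart + E),      # donor boundary d
    a1 = as.integer(gstart + E + I),      # canonical acceptor boundary
    a2 = NA_integer_,
    traj_row = c(seq_len(design$n_ir_genes), seq_len(design$n_psi_genes))
  )
  if (design$n_psi_genes > 0) {
    is_psi <- layout$type == "psi"
    layout$a2[is_psi] <- layout$a1[is_psi] - as.integer(design$alt_offsets)
  }
  layout
}

#' Write the synthetic genome: FASTA, GFF3 annotation and repeat BED
#'
#' @param design A `sim_design` object.
#' @param dir Output directory (created if needed).
#' @param repeats Optional tibble `chrom`, `start`, `end` (0-based
#'   half-open) of repeat intervals; the default places one repeat in the
#'   intergenic spacer upstream of the first gene.
#' @return List: `fasta`, `gff3`, `bed` (paths), `layout` (gene layout
#'   tibble), `chrom_len`.
#' @export
make_genome <- function(design, dir, repeats = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- sim_gene_layout(design)
  chrom_len <- max(layout$gend) + 500L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)
  seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  if (design$stopfree_insertion) {
    # alternate-retained intervals get a sequence whose six frames only
    # ever read GCT/CTG/TGC (forward) and AGC/GCA/CAG (reverse): stop-free
    for (i in which(layout$type == "psi")) {
      idx <- seq.int(layout$a2[i] + 1L, layout$a1[i])
      seq[idx] <- rep(c("G", "C", "T"), length.out = length(idx))
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- "chrS"
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta)

  gff3 <- file.path(dir, "annotation.gff3")
  write_sim_gff3(layout, gff3, chrom_len)

  if (is.null(repeats)) {
    repeats <- tibble::tibble(chrom = "chrS", start = 100L, end = 200L)
  }
  bed <- file.path(dir, "repeats.bed")
  readr::write_tsv(repeats, bed, col_names = FALSE)

  list(fasta = fasta, gff3 = gff3, bed = bed, layout = layout,
       chrom_len = chrom_len)
}

write_sim_gff3 <- function(layout, path, chrom_len) {
  rows <- purrr::pmap(layout, function(gene_id, type, strand, chrom,
                                       gstart, gend, e1_end, a1, a2,
                                       traj_row) {
    tx <- paste0(gene_id, ".t1")
    tibble::tibble(
      chrom = chrom,
      type = c("gene", "mRNA", "exon", "exon"),
      start = c(gstart, gstart, gstart, a1) + 1L,  # to 1-based inclusive
      end = c(gend, gend, e1_end, gend),
      strand = strand,
      ID = c(gene_id, tx, NA, NA),
      Parent = c(NA, gene_id, tx, tx)
    )
  })
  feats <- dplyr::bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand
  )
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(feats$Parent, function(p) if (is.na(p)) character(0) else p)
  )
  GenomeInfoDb::seqlengths(gr) <- c(chrS = chrom_len)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# closed-form expected observed values from the placement geometry
sim_truth <- function(design, layout) {
  L <- design$read_length
  E <- design$exon_length; I <- design$intron_length
  samples <- sim_samples(design)
  tps <- unique(samples[, c("timepoint", "hours")])
  purrr::pmap(layout, function(gene_id, type, strand, chrom, gstart, gend,
                               e1_end, a1, a2, traj_row) {
    if (type == "ir") {
      r <- design$ir_trajectories[traj_row, ]
      Ls <- 2 * E           # spliced isoform length
      Lr <- 2 * E + I       # retained isoform length
      q_sj <- (L - 1) / (Ls - L + 1)
      q_ie <- (L - 2 * 10 + 1) / (Lr - L + 1)
      expected <- r * 2 * q_ie / (r * 2 * q_ie + (1 - r) * q_sj)
      metric <- "PIR"
      truth <- r
    } else {
      p <- design$psi_trajectories[traj_row, ]
      LA <- 2 * E                      # canonical-acceptor isoform
      LB <- 2 * E + (a1 - a2)          # alternate keeps (a2, a1)
      qA <- (L - 2 * 8 + 1) / (LA - L + 1)
      qB <- (L - 2 * 8 + 1) / (LB - L + 1)
      expected <- p * qB / (p * qB + (1 - p) * qA)
      metric <- "PSI"
      truth <- p
    }
    tibble::tibble(
      gene_id = gene_id, type = type, metric = metric,
      timepoint = tps$timepoint, hours = tps$hours,
      truth = truth, expected = expected
    )
  }) |>
    dplyr::bind_rows()
}

#' Simulate spliced alignments for every sample of a design
#'
#' For each sample and gene, `depth` fragments are drawn from the
#' intron-retained (or alternate-acceptor) isoform with the gene's
#' per-timepoint truth probability and placed uniformly along the chosen
#' isoform; spliced reads carry alignment gaps exactly at the isoform's
#' intron boundaries. A `frac_low_mapq` fraction of reads is emitted with
#' MAPQ 0 to exercise the mapping-quality filter; all others have MAPQ 60.
#'
#' @param design A `sim_design` object.
#' @param genome Output of [make_genome()].
#' @param dir Output directory for BAM files and TSV tables.
#' @return List: `samples` (sample sheet with a `bam` column), `truth`
#'   (gene-by-timepoint truth and analytic expected observed values),
#'   `design_path`, `truth_path`.
#' @export
simulate_reads <- function(design, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- genome$layout
  L <- design$read_length
  if (L > 2 * design$exon_length) {
    stop("read length exceeds the spliced isoform length", call. = FALSE)
  }
  chrom_seq <- Biostrings::readDNAStringSet(genome$fasta)[[1]]
  samples <- sim_samples(design)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed + 1L)

  bam_paths <- character(nrow(samples))
  for (s in seq_len(nrow(samples))) {
    recs <- purrr::pmap(layout, function(gene_id, type, strand, chrom,
                                         gstart, gend, e1_end, a1, a2,
                                         traj_row) {
      tp_idx <- match(samples$hours[s], design$timepoints)
      p_alt <- if (type == "ir") design$ir_trajectories[traj_row, tp_idx]
               else design$psi_trajectories[traj_row, tp_idx]
      n <- design$depth
      alt <- stats::runif(n) < p_alt
      sim_gene_reads(n, alt, type, gstart, e1_end, a1, a2, gend, L,
                     gene_id)
    })
    recs <- dplyr::bind_rows(recs)
    recs$mapq <- ifelse(stats::runif(nrow(recs)) < design$frac_low_mapq,
                        0L, 60L)
    recs$qname <- sprintf("%s_%s_%06d", samples$sample_id[s],
                          recs$gene_id, seq_len(nrow(recs)))
    bam_paths[s] <- write_sam_bam(
      recs, chrom = "chrS", chrom_len = genome$chrom_len,
      chrom_seq = chrom_seq,
      out_prefix = file.path(dir, samples$sample_id[s])
    )
  }
  samples$bam <- bam_paths

  truth <- sim_truth(design, layout)
  design_path <- file.path(dir, "design.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(samples, design_path)
  readr::write_tsv(truth, truth_path)
  list(samples = samples, truth = truth, design_path = design_path,
       truth_path = truth_path)
}

# uniform placement of n reads on the chosen isoform of one gene; returns
# pos (0-based) and cigar per read
sim_gene_reads <- function(n, alt, type, gstart, e1_end, a1, a2, gend, L,
                           gene_id) {
  E1 <- e1_end - gstart
  res <- vector("list", n)
  for (i in seq_len(n)) {
    if (type == "ir" && alt[i]) {
      # retained isoform: contiguous genomic sequence
      iso_len <- gend - gstart
      u <- sample.int(iso_len - L + 1L, 1L) - 1L
      pos <- gstart + u
      cigar <- paste0(L, "M")
    } else {
      # spliced isoform: exon1 + downstream exon starting at the acceptor
      acc <- if (type == "psi" && alt[i]) a2 else a1
      iso_len <- E1 + (gend - acc)
      u <- sample.int(iso_len - L + 1L, 1L) - 1L
      if (u + L <= E1) {                 # fully in exon 1
        pos <- gstart + u
        cigar <- paste0(L, "M")
      } else if (u >= E1) {              # fully downstream
        pos <- acc + (u - E1)
        cigar <- paste0(L, "M")
      } else {                           # spans the junction
        left <- E1 - u
        pos <- gstart + u
        cigar <- paste0(left, "M", acc - e1_end, "N", L - left, "M")
      }
    }
    res[[i]] <- c(pos = pos, cigar = cigar)
  }
  tibble::tibble(
    gene_id = gene_id,
    pos = as.integer(vapply(res, `[[`, character(1), "pos")),
    cigar = vapply(res, `[[`, character(1), "cigar")
  )
}

# write records as coordinate-sorted SAM, convert to indexed BAM
write_sam_bam <- function(recs, chrom, chrom_len, chrom_seq, out_prefix) {
  recs <- recs[order(recs$pos), ]
  seqs <- vapply(seq_len(nrow(recs)), function(i) {
    read_sequence(chrom_seq, recs$pos[i], recs$cigar[i])
  }, character(1))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
    sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            recs$qname, chrom, recs$pos + 1L, recs$mapq, recs$cigar, seqs)
  )
  sam <- paste0(out_prefix, ".sam")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# reference sequence of the aligned blocks (gaps spliced out)
read_sequence <- function(chrom_seq, pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MN]", cigar))[[1]]
  lens <- as.integer(sub("[MN]", "", ops))
  kinds <- sub("\\d+", "", ops)
  cur <- pos
  parts <- character(0)
  for (k in seq_along(ops)) {
    if (kinds[k] == "M") {
      parts <- c(parts,
                 as.character(Biostrings::subseq(chrom_seq, cur + 1L,
                                                 cur + lens[k])))
    }
    cur <- cur + lens[k]
  }
  paste(parts, collapse = "")
}

#' Simulate a complete dataset (genome plus per-sample alignments)
#'
#' @param design A `sim_design` object.
#' @param dir Output directory.
#' @param repeats Optional repeat intervals passed to [make_genome()].
#' @return List combining [make_genome()] and [simulate_reads()] outputs.
#' @export
simulate_dataset <- function(design, dir, repeats = NULL) {
  genome <- make_genome(design, dir, repeats = repeats)
  reads <- simulate_reads(design, genome, dir)
  c(genome, reads)
}
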