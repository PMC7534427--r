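# Shared alignment access. Reads are loaded once per BAM as a GAlignments
# with qname/flag/mapq; secondary, supplementary and unmapped records are
# dropped here so every counter sees the same read set.

read_alignments <- function(path, min_mapq = 0L) {
  path <- normalizePath(path, mustWork = TRUE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("missing BAM index for '", path, "'; run indexBam() first",
         call. = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("qname", "flag", "mapq"))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  if (min_mapq > 0) {
    mq <- S4Vectors::mcols(ga)$mapq
    ga <- ga[!is.na(mq) & mq >= min_mapq]
  }
  ga
}

# Aligned reference segments per read, split at N (intron) gaps only.
read_segments <- function(ga) {
  GenomicAlignments::grglist(ga, order.as.in.query = FALSE)
}

check_chroms <- function(ga, chroms) {
  missing <- setdiff(unique(chroms), GenomeInfoDb::seqlevels(ga))
  if (length(missing) > 0) {
    stop("chromosome(s) absent from alignment header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
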