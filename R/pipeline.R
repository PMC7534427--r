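# End-to-end wrappers chaining the per-module functions; these are what
# the command-line interface and the worked examples call.

#' Run the intron-retention pipeline over a set of samples
#'
#' Counts intron evidence per sample, averages replicates, applies the
#' filter cascade and builds the PIR matrix.
#'
#' @param samples Sample sheet tibble with columns `sample_id`,
#'   `timepoint`, `replicate` and `bam` (path to the sample's indexed
#'   alignments).
#' @param gene_models Tibble from [load_annotation()].
#' @param min_mapq,min_anchor Read filters for [count_intron_evidence()].
#' @param min_sj,min_ie,min_cov,min_intron_reads,insufficient_as_zero
#'   Filter cascade for [compute_pir()].
#' @param min_pir,pseudo Matrix construction parameters
#'   ([build_pir_matrix()]).
#' @return List: `introns`, `counts` (per sample), `quants` (per
#'   timepoint, with PIR and status), `matrix`.
#' @export
run_pir <- function(samples, gene_models, min_mapq = 10, min_anchor = 10,
                    min_sj = 5, min_ie = 2, min_cov = 1.0,
                    min_intron_reads = 5, insufficient_as_zero = FALSE,
                    min_pir = 0.05, pseudo = 0.001) {
  introns <- derive_introns(gene_models)
  counts <- purrr::map2(samples$bam, samples$sample_id, function(b, id) {
    count_intron_evidence(b, introns, sample_id = id, min_mapq = min_mapq,
                          min_anchor = min_anchor)
  }) |>
    dplyr::bind_rows()
  quants <- average_replicates(counts, samples) |>
    compute_pir(min_sj = min_sj, min_ie = min_ie, min_cov = min_cov,
                min_intron_reads = min_intron_reads,
                insufficient_as_zero = insufficient_as_zero)
  mat <- build_pir_matrix(quants, samples, min_pir = min_pir,
                          pseudo = pseudo)
  list(introns = introns, counts = counts, quants = quants, matrix = mat)
}

#' Run the splice-junction PSI pipeline over a set of samples
#'
#' Extracts junctions per sample, applies the junction filters, groups
#' junctions into local splicing events, computes PSI, annotates roles,
#' drops noisy events and builds the PSI matrix.
#'
#' @param samples Sample sheet tibble with `sample_id`, `timepoint`,
#'   `replicate`, `bam`.
#' @param gene_models Tibble from [load_annotation()].
#' @param repeats Optional repeat intervals from [load_repeats()].
#' @param min_overhang,min_mapq,min_intron_len,max_intron_len Junction
#'   extraction parameters ([extract_junctions()]).
#' @param min_reads Junction support filter ([filter_junctions()]).
#' @param min_alt_psi,min_alt_reads Event noise filters
#'   ([filter_events()]).
#' @param pseudo Matrix pseudo-count ([build_psi_matrix()]).
#' @return List: `junctions` (raw), `filtered`, `events`, `psi` (long,
#'   role-annotated and event-filtered), `matrix`.
#' @export
run_psi <- function(samples, gene_models, repeats = NULL,
                    min_overhang = 8, min_mapq = 0, min_intron_len = 10,
                    max_intron_len = 3000, min_reads = 2,
                    min_alt_psi = 0.05, min_alt_reads = 2,
                    pseudo = 0.0001) {
  junctions <- purrr::map2(samples$bam, samples$sample_id,
                           function(b, id) {
    extract_junctions(b, sample_id = id, min_overhang = min_overhang,
                      min_mapq = min_mapq, min_intron_len = min_intron_len,
                      max_intron_len = max_intron_len)
  }) |>
    dplyr::bind_rows()
  filtered <- filter_junctions(junctions, samples, repeats = repeats,
                               min_reads = min_reads)
  events <- group_events(filtered, gene_models)
  psi <- compute_psi(events, filtered, samples) |>
    annotate_roles() |>
    filter_events(min_alt_psi = min_alt_psi, min_alt_reads = min_alt_reads)
  mat <- build_psi_matrix(psi, samples, pseudo = pseudo)
  list(junctions = junctions, filtered = filtered, events = events,
       psi = psi, matrix = mat)
}
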