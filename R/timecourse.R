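# Time-course clustering of PSI/PIR matrices: k-means with restarts, elbow
# diagnostics, hierarchical ordering of timepoints from the centroids, and
# per-cluster summaries.

#' Drop matrix rows containing missing values
#'
#' @param mat Wide matrix tibble.
#' @return The matrix without rows having any `NA` cell; the number of
#'   removed rows is reported with a message.
#' @export
drop_incomplete_rows <- function(mat) {
  vals <- matrix_values(mat)
  keep <- rowSums(is.na(vals)) == 0
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values removed")
  }
  mat[keep, ]
}

#' K-means clustering of splicing trajectories
#'
#' Lloyd iterations with Euclidean distance; the best of `restarts` random
#' initialisations by total within-cluster sum of squares is kept.
#' Deterministic given `seed`.
#'
#' @param mat Wide matrix tibble without missing values.
#' @param k Number of clusters, `1 <= k <= nrow(mat)`.
#' @param seed RNG seed.
#' @param restarts Number of random initialisations.
#' @return A `cycle_kmeans` object: list with `k`, `assignments` (tibble
#'   `row_id`, `cluster`), `centroids` (tibble `cluster` plus timepoint
#'   columns), `wss` (total within-cluster sum of squares), `withinss`,
#'   `totss`, `sizes`, `seed`, `restarts`, `timepoints`, `metric`.
#' @export
kmeans_cluster <- function(mat, k, seed = 42, restarts = 25) {
  m <- matrix_values(mat)
  if (any(is.na(m))) {
    stop("matrix contains missing values; drop_incomplete_rows() first",
         call. = FALSE)
  }
  if (k < 1 || k > nrow(m)) {
    stop("k must be between 1 and the number of rows (", nrow(m), ")",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # fewer distinct profiles than clusters: every cluster is pure, wss 0
  key <- apply(m, 1, paste, collapse = "\r")
  u <- unique(key)
  if (length(u) < k) {
    cl <- match(key, u)
    centers <- m[match(u, key), , drop = FALSE]
    centers <- centers[c(seq_along(u),
                         rep(length(u), k - length(u))), , drop = FALSE]
    return(structure(list(
      k = k,
      assignments = tibble::tibble(row_id = rownames(m),
                                   cluster = cl),
      centroids = dplyr::bind_cols(
        tibble::tibble(cluster = seq_len(k)),
        tibble::as_tibble(as.data.frame(centers))
      ),
      wss = 0, withinss = rep(0, k), totss = sum(scale(m, scale = FALSE)^2),
      sizes = tabulate(cl, k), seed = seed, restarts = restarts,
      timepoints = colnames(m), metric = attr(mat, "metric")
    ), class = "cycle_kmeans"))
  }
  # best of `restarts` Lloyd runs; a rare empty-cluster start is skipped
  km <- NULL
  for (i in seq_len(restarts)) {
    cand <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = k, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (!is.null(cand) &&
        (is.null(km) || cand$tot.withinss < km$tot.withinss)) {
      km <- cand
    }
  }
  if (is.null(km)) {
    stop("k-means failed for every initialisation", call. = FALSE)
  }
  structure(list(
    k = k,
    assignments = tibble::tibble(row_id = rownames(m),
                                 cluster = unname(km$cluster)),
    centroids = dplyr::bind_cols(
      tibble::tibble(cluster = seq_len(k)),
      tibble::as_tibble(as.data.frame(km$centers))
    ),
    wss = km$tot.withinss,
    withinss = km$withinss,
    totss = km$totss,
    sizes = km$size,
    seed = seed,
    restarts = restarts,
    timepoints = colnames(m),
    metric = attr(mat, "metric")
  ), class = "cycle_kmeans")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.cycle_kmeans <- function(x, ...) {
  cat(sprintf(
    "k-means clustering of %d %s trajectories into k = %d clusters\n",
    nrow(x$assignments), x$metric %||% "splicing", x$k))
  cat(sprintf("cluster sizes: %s\n", paste(x$sizes, collapse = ", ")))
  cat(sprintf("total within-cluster SS: %.6g (of total SS %.6g)\n",
              x$wss, x$totss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cluster component summaries of a k-means fit
#'
#' @param x A `cycle_kmeans` object.
#' @param ... Unused.
#' @return Tibble with one row per cluster: `cluster`, `size`, `withinss`,
#'   and the centroid value at each timepoint.
#' @export
tidy.cycle_kmeans <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k), size = x$sizes,
                   withinss = x$withinss),
    x$centroids[, -1, drop = FALSE]
  )
}

#' One-row fit summary of a k-means result
#'
#' @param x A `cycle_kmeans` object.
#' @param ... Unused.
#' @return Tibble: `k`, `n_rows`, `totss`, `tot_withinss`, `betweenss`.
#' @export
glance.cycle_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_rows = nrow(x$assignments), totss = x$totss,
    tot_withinss = x$wss, betweenss = x$totss - x$wss
  )
}

#' Centroid trajectory plot of a k-means fit
#'
#' @param object A `cycle_kmeans` object.
#' @param ... Unused.
#' @return A ggplot of centroid values across timepoints, one line per
#'   cluster.
#' @export
autoplot.cycle_kmeans <- function(object, ...) {
  long <- object$centroids |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint",
                        values_to = "value") |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = object$timepoints))
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value,
                                     group = factor(.data$cluster),
                                     colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timepoint", y = object$metric %||% "value",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Within-cluster sum of squares over a range of k
#'
#' @param mat Wide matrix tibble without missing values.
#' @param k_range Integer vector of cluster counts; values above the row
#'   count are skipped with a warning.
#' @param seed,restarts Passed to [kmeans_cluster()] for each k.
#' @return Tibble `k`, `wss`.
#' @export
elbow_curve <- function(mat, k_range = 1:20, seed = 42, restarts = 25) {
  n <- nrow(mat)
  if (n == 0) stop("matrix is empty", call. = FALSE)
  usable <- k_range[k_range <= n]
  if (length(usable) < length(k_range)) {
    warning("k values above the row count (", n, ") were skipped")
  }
  tibble::tibble(
    k = usable,
    wss = purrr::map_dbl(usable, function(k) {
      kmeans_cluster(mat, k, seed = seed, restarts = restarts)$wss
    })
  )
}

#' Elbow diagnostic plot
#'
#' @param curve Tibble from [elbow_curve()].
#' @return A ggplot of total within-cluster sum of squares against k.
#' @export
plot_elbow <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k",
                  y = "total within-cluster sum of squares") +
    ggplot2::theme_minimal()
}

#' Hierarchical clustering of timepoints from cluster centroids
#'
#' Timepoint columns of the centroid matrix are clustered agglomeratively
#' (Euclidean distance, complete linkage by default), yielding the leaf
#' order used for heatmap export.
#'
#' @param fit A `cycle_kmeans` object (or a centroid tibble whose first
#'   column is `cluster`).
#' @param method Linkage passed to [stats::hclust()].
#' @return List with the `hclust` tree and `leaf_order`, a permutation of
#'   the timepoints.
#' @export
cluster_timepoints <- function(fit, method = "complete") {
  centroids <- if (inherits(fit, "cycle_kmeans")) fit$centroids else fit
  m <- t(as.matrix(centroids[, -1, drop = FALSE]))
  hc <- stats::hclust(stats::dist(m), method = method)
  list(hclust = hc, leaf_order = rownames(m)[hc$order])
}

#' Per-cluster, per-timepoint summaries
#'
#' @param mat Wide matrix tibble the clustering was run on.
#' @param assignments Tibble `row_id`, `cluster` (from a `cycle_kmeans`
#'   fit).
#' @param ci_level Confidence level for the normal-approximation interval
#'   `mean +/- z * SE`.
#' @return Tibble: `cluster`, `timepoint`, `n`, `mean`, `sd`, `se`,
#'   `ci_lower`, `ci_upper`. Single-row clusters have `sd = se = 0`.
#' @export
cluster_summary <- function(mat, assignments, ci_level = 0.95) {
  z <- stats::qnorm((1 + ci_level) / 2)
  long <- mat |>
    tidyr::pivot_longer(-1, names_to = "timepoint", values_to = "value") |>
    dplyr::rename(row_id = 1) |>
    dplyr::inner_join(assignments, by = "row_id")
  long |>
    dplyr::group_by(.data$cluster, .data$timepoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      timepoint = factor(.data$timepoint, levels = names(mat)[-1]),
      se = .data$sd / sqrt(.data$n),
      ci_lower = .data$mean - z * .data$se,
      ci_upper = .data$mean + z * .data$se
    ) |>
    dplyr::arrange(.data$cluster, .data$timepoint)
}

#' Expression fold change relative to the gene's mean
#'
#' @param rpkm Wide tibble: `gene_id` plus one RPKM column per timepoint.
#' @param gene_ids Genes to include; all must be present in the table.
#' @return Tibble of the same shape with each gene's values divided by its
#'   mean across timepoints. Genes with all-zero RPKM get `NA` fold
#'   changes and are reported with a message.
#' @export
expression_foldchange <- function(rpkm, gene_ids = rpkm$gene_id) {
  missing <- setdiff(gene_ids, rpkm$gene_id)
  if (length(missing) > 0) {
    stop("gene(s) absent from RPKM table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- rpkm[match(gene_ids, rpkm$gene_id), ]
  vals <- as.matrix(sub[, -1, drop = FALSE])
  means <- rowMeans(vals)
  zero <- means == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with all-zero RPKM set to NA")
  }
  fc <- sweep(vals, 1, means, "/")
  fc[zero, ] <- NA_real_
  dplyr::bind_cols(tibble::tibble(gene_id = sub$gene_id),
                   tibble::as_tibble(as.data.frame(fc)))
}
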