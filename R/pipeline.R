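#' Population structure from k-mer frequencies
#'
#' End-to-end pipeline: count canonical k-mers per sample, drop k-mers
#' below `min_count`, intersect profiles across samples, build the shared
#' count matrix, standardize, run PCA, scan K-means inertia over
#' `1..k_max`, pick the cluster number at the elbow, cluster on the first
#' `n_pcs` principal components, and (when labels are available) score the
#' clustering against them with adjusted mutual information.
#'
#' Clustering uses the first two PCs by default: with many samples the
#' variance of a k-mer matrix tends to spread thinly over many components,
#' and feeding all components up to 80% cumulative variance into K-means
#' can leave the inertia scree without a usable elbow, while the two
#' leading components give stable, interpretable clusters. Use
#' `cluster_on = "cumvar"` to cluster on the components reaching
#' `target_var` instead.
#'
#' @param samples Sample table (tibble with `sample_id` plus `sequence` or
#'   `path`, optional `label`) or the path of a manifest TSV.
#' @param k K-mer length in bp.
#' @param min_count Minimum per-sample k-mer count (default 2: singleton
#'   filtering).
#' @param n_pcs Number of leading PCs to cluster on (default 2).
#' @param k_max Largest cluster number scanned (default 10).
#' @param seed Integer seed controlling K-means restarts.
#' @param cluster_on `"n_pcs"` (default) or `"cumvar"`.
#' @param target_var Cumulative explained-variance target used for
#'   reporting and for `cluster_on = "cumvar"` (default 0.80).
#' @param scale_method Passed to [scale_features()].
#' @param elbow_method Passed to [elbow_k()] (default `"chord"`).
#' @return A `kmer_structure` object; see [tidy.kmer_structure()] and
#'   [glance.kmer_structure()].
#' @examples
#' \donttest{
#' cfg <- scenario_config("three-pop", scale = 0.005, seed = 1)
#' fit <- wf_simulate(cfg) |> kmer_structure(k = 9, seed = 1)
#' glance(fit)
#' }
#' @export
kmer_structure <- function(samples, k, min_count = 2L, n_pcs = 2L,
                           k_max = 10L, seed = 1L,
                           cluster_on = c("n_pcs", "cumvar"),
                           target_var = 0.80,
                           scale_method = c("zscore", "minmax"),
                           elbow_method = c("chord", "second_diff")) {
  cluster_on <- match.arg(cluster_on)
  elbow_method <- match.arg(elbow_method)
  scale_method <- match.arg(scale_method)
  if (is.character(samples) && length(samples) == 1L) {
    samples <- read_manifest(samples)
  }
  stopifnot(is.data.frame(samples))
  n <- nrow(samples)
  if (n < 3L) stop("pipeline needs at least 3 samples", call. = FALSE)
  stop_if_not_scalar_count(n_pcs, "n_pcs")
  if (n_pcs > n - 1L) {
    stop("`n_pcs` must be <= number of samples - 1", call. = FALSE)
  }

  profiles <- kmer_profiles(samples, k = k, min_count = min_count)
  mat <- kmer_count_matrix(profiles)
  scaled <- scale_features(mat, method = scale_method)
  pca <- kmer_pca(scaled)
  n_pcs_cumvar <- select_n_components(pca$evr, target = target_var)
  dims <- if (cluster_on == "n_pcs") seq_len(n_pcs) else seq_len(
    min(n_pcs_cumvar, ncol(pca$scores)))
  points <- pca$scores[, dims, drop = FALSE]

  scan <- elbow_scan(points, k_max = min(k_max, n), seed = seed)
  choice <- elbow_k(scan, method = elbow_method)
  clusters <- cluster_kmeans(points, choice$k, seed = seed)

  labels <- sample_labels(samples)
  ami_score <- if (!is.null(labels) && !anyNA(labels)) {
    ami(labels, clusters$labels)
  } else NA_real_

  structure(list(
    samples = tibble::tibble(sample_id = samples$sample_id,
                             label = labels %||% NA_character_),
    matrix = mat, scaled = scaled, pca = pca, elbow = scan,
    elbow_choice = choice, clusters = clusters, ami = ami_score,
    n_pcs_cumvar = n_pcs_cumvar,
    params = list(k = k, min_count = min_count, n_pcs = n_pcs,
                  k_max = k_max, seed = seed, cluster_on = cluster_on,
                  target_var = target_var, scale_method = scale_method,
                  elbow_method = elbow_method)
  ), class = "kmer_structure")
}

#' @export
print.kmer_structure <- function(x, ...) {
  g <- glance(x)
  cat("# kmer_structure: ", g$n_samples, " samples, ", g$n_features,
      " shared k-mers (k = ", x$params$k, ")\n", sep = "")
  cat("  K = ", g$K, " (elbow strength ", signif(g$elbow_strength, 3),
      if (g$weak_elbow) ", weak" else "", ")", sep = "")
  if (!is.na(g$ami)) cat(", AMI vs labels = ", signif(g$ami, 4), sep = "")
  cat("\n  PC1 ", sprintf("%.1f%%", 100 * g$var_pc1),
      ", PC2 ", sprintf("%.1f%%", 100 * g$var_pc2),
      " of variance; ", g$n_pcs_cumvar, " PCs reach ",
      sprintf("%.0f%%", 100 * x$params$target_var), "\n", sep = "")
  invisible(x)
}

#' Tidy and summarise k-mer structure results
#'
#' `tidy()` returns one row per sample with its PC scores, assigned cluster
#' and (if known) label; `glance()` returns a one-row model summary.
#'
#' @param x A `kmer_structure` (for `tidy.kmer_matrix`, a `kmer_matrix`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kmer_structure <- function(x, ...) {
  dplyr::bind_cols(
    x$samples,
    tibble::tibble(cluster = x$clusters$labels),
    tibble::as_tibble(x$pca$scores)
  )
}

#' @rdname tidy.kmer_structure
#' @export
glance.kmer_structure <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_features = ncol(x$matrix),
    K = x$clusters$K,
    ami = x$ami,
    inertia = x$clusters$inertia,
    elbow_strength = x$elbow_choice$strength,
    weak_elbow = x$elbow_choice$weak,
    var_pc1 = x$pca$evr[1L],
    var_pc2 = if (length(x$pca$evr) >= 2L) x$pca$evr[2L] else NA_real_,
    n_pcs_cumvar = x$n_pcs_cumvar
  )
}

#' @rdname tidy.kmer_structure
#' @export
tidy.kmer_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id")
}

#' @rdname tidy.kmer_structure
#' @export
glance.kmer_pca <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$scores),
                 var_pc1 = x$evr[1L],
                 cum_var = sum(x$evr[seq_len(ncol(x$scores))]))
}

#' Plot methods for structure results
#'
#' `autoplot.kmer_structure()` draws the PC1/PC2 scatter coloured by
#' assigned cluster (shape = known label, when present);
#' `autoplot.elbow_scan()` draws the inertia scree with the detected elbow.
#'
#' @param object A `kmer_structure` or `elbow_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kmer_structure <- function(object, ...) {
  d <- tidy(object)
  d$cluster <- factor(d$cluster)
  pt <- if (all(is.na(d$label))) {
    ggplot2::geom_point(size = 2.5)
  } else {
    ggplot2::geom_point(size = 2.5, ggplot2::aes(shape = .data$label))
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = .data$cluster)) +
    pt +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$pca$evr[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$pca$evr[2L]),
      colour = "cluster", shape = "label"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kmer_structure
#' @export
autoplot.elbow_scan <- function(object, ...) {
  choice <- elbow_k(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = choice$k, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "number of clusters k", y = "K-means inertia") +
    ggplot2::theme_minimal()
}
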