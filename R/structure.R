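#' Standardize a sample-by-feature matrix
#'
#' Per-feature z-scoring with the population standard deviation (divisor
#' `n`), i.e. the behaviour of scikit-learn's `StandardScaler`: PCA weights
#' features by their variance, so without this step high-count k-mers would
#' dominate the projection. Constant features are mapped to all-zero columns
#' (their count is recorded) rather than dropped, so the feature space is
#' stable. Min-max scaling to \[0, 1\] is available as an alternative.
#'
#' @param x A `kmer_matrix` or numeric matrix (samples x features).
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return A `scaled_matrix`: list with `values` (numeric matrix),
#'   `feature_means`, `feature_sds` (population sd), `method`, `n_constant`.
#' @export
scale_features <- function(x, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  m <- unclass(x)
  attr(m, "k") <- NULL
  attr(m, "min_count") <- NULL
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("standardization needs at least 2 samples", call. = FALSE)
  mu <- colMeans(m)
  if (method == "zscore") {
    sds <- sqrt(colMeans(sweep(m, 2L, mu)^2))
    const <- sds == 0
    vals <- sweep(m, 2L, mu)
    vals[, !const] <- sweep(vals[, !const, drop = FALSE], 2L, sds[!const], "/")
    vals[, const] <- 0
  } else {
    lo <- apply(m, 2L, min)
    hi <- apply(m, 2L, max)
    const <- hi == lo
    sds <- hi - lo
    vals <- sweep(m, 2L, lo)
    vals[, !const] <- sweep(vals[, !const, drop = FALSE], 2L, sds[!const], "/")
    vals[, const] <- 0
  }
  if (any(const)) {
    message(sum(const), " constant feature(s) standardized to zero")
  }
  structure(list(values = vals, feature_means = mu, feature_sds = sds,
                 method = method, n_constant = sum(const)),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat("# scaled_matrix (", x$method, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " features, ", x$n_constant, " constant\n", sep = "")
  invisible(x)
}

#' Principal component analysis of a k-mer count matrix
#'
#' Singular-value decomposition of the column-centered data. The explained
#' variance ratio of each component is its share of the total variance of
#' the input. Component signs are fixed so that the largest-magnitude
#' loading of each component is positive, making results platform-stable.
#'
#' @param x A `scaled_matrix`, `kmer_matrix` or numeric matrix.
#' @param n_components Number of components to keep; default
#'   `min(n_samples - 1, n_features)`.
#' @return A `kmer_pca`: list with `scores` (samples x components),
#'   `rotation` (features x components; its transpose has orthonormal rows),
#'   `evr` (explained variance ratio, all components), `sdev`, `center`.
#' @export
kmer_pca <- function(x, n_components = NULL) {
  m <- if (inherits(x, "scaled_matrix")) x$values else {
    m0 <- unclass(x); attr(m0, "k") <- NULL; attr(m0, "min_count") <- NULL
    as.matrix(m0)
  }
  storage.mode(m) <- "double"
  n <- nrow(m); p <- ncol(m)
  max_nc <- min(n - 1L, p)
  if (max_nc < 1L) stop("PCA needs at least 2 samples and 1 feature", call. = FALSE)
  n_components <- n_components %||% max_nc
  stop_if_not_scalar_count(n_components, "n_components")
  if (n_components > max_nc) {
    stop("`n_components` must be <= min(samples - 1, features) = ", max_nc,
         call. = FALSE)
  }
  center <- colMeans(m)
  mc <- sweep(m, 2L, center)
  sv <- svd(mc, nu = n_components, nv = n_components)
  tot <- sum(sv$d^2)
  if (tot <= 0) {
    warning("matrix has zero total variance; PCA scores are all zero",
            call. = FALSE)
    evr <- rep(0, max_nc)
  } else {
    evr <- (sv$d^2 / tot)[seq_len(max_nc)]
  }
  rotation <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pc <- paste0("PC", seq_len(n_components))
  dimnames(scores) <- list(rownames(m), pc)
  dimnames(rotation) <- list(colnames(m), pc)
  structure(list(scores = scores, rotation = rotation, evr = evr,
                 sdev = sv$d[seq_len(max_nc)] / sqrt(max(n - 1L, 1L)),
                 center = center),
            class = "kmer_pca")
}

#' @export
print.kmer_pca <- function(x, ...) {
  cat("# kmer_pca: ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components kept\n", sep = "")
  cat("  explained variance ratio: ",
      paste(sprintf("%.3f", head(x$evr, 5L)), collapse = " "),
      if (length(x$evr) > 5L) " ...", "\n", sep = "")
  invisible(x)
}

#' Number of components reaching a cumulative variance target
#'
#' @param evr Explained variance ratios, non-increasing.
#' @param target Cumulative target in (0, 1\]; default 0.80.
#' @return Smallest n with cumulative ratio >= `target`; the full length,
#'   with a warning, if the target is never reached.
#' @export
select_n_components <- function(evr, target = 0.80) {
  if (!length(evr)) stop("`evr` is empty", call. = FALSE)
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target > 1) {
    stop("`target` must be in (0, 1]", call. = FALSE)
  }
  cs <- cumsum(evr)
  hit <- which(cs >= target - 1e-12)
  if (!length(hit)) {
    warning("cumulative explained variance reaches only ",
            sprintf("%.3f", cs[length(cs)]), " < ", target, call. = FALSE)
    return(length(evr))
  }
  hit[1L]
}

# k-means++ seeding: first center uniform, then points with prob ~ D^2.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
    for (j in 2:K) {
      if (sum(d2) <= 0) {
        # all remaining points coincide with a chosen center
        centers[j:K] <- sample.int(n, K - j + 1L, replace = TRUE)
        break
      }
      centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j], ])^2))
    }
  }
  x[centers, , drop = FALSE]
}

# Nearest-center assignment with ties broken by lowest center index.
assign_nearest <- function(x, centers) {
  d <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  apply(d, 1L, which.min)
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd's algorithm (via [stats::kmeans()]) from k-means++ initialisations;
#' the best-inertia solution over `restarts` is kept. Deterministic given
#' `seed`. Cluster labels are canonicalised by first appearance in sample
#' order, so output is invariant to internal label permutations.
#'
#' @param x Numeric matrix of points (samples x dims).
#' @param K Number of clusters (<= number of points).
#' @param seed Integer RNG seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A `kmeans_fit`: list with `K`, `labels` (1..K), `centers`,
#'   `inertia`.
#' @export
cluster_kmeans <- function(x, K, seed = 1L, restarts = 10L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stop_if_not_scalar_count(K, "K")
  if (K > nrow(x)) stop("`K` must be <= number of points", call. = FALSE)
  n_distinct <- nrow(unique(x))
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(x, K)
      if (n_distinct < K || anyDuplicated(init)) {
        # degenerate data: assign directly, no Lloyd iterations possible
        lab <- assign_nearest(x, init)
        cen <- init
        for (j in unique(lab)) cen[j, ] <- colMeans(x[lab == j, , drop = FALSE])
        lab <- assign_nearest(x, cen)
        inertia <- sum((x - cen[lab, , drop = FALSE])^2)
        fit <- list(cluster = lab, centers = cen, tot.withinss = inertia)
      } else {
        fit <- suppressWarnings(
          stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd")
        )
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- as.integer(best$cluster)
  relabel <- match(labels, unique(labels))  # first-appearance order
  centers <- best$centers[unique(labels), , drop = FALSE]
  rownames(centers) <- NULL
  structure(list(K = as.integer(K), labels = relabel, centers = centers,
                 inertia = best$tot.withinss, seed = seed,
                 restarts = as.integer(restarts)),
            class = "kmeans_fit")
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat("# kmeans_fit: K = ", x$K, ", inertia = ", signif(x$inertia, 6),
      "\n", sep = "")
  invisible(x)
}

#' Inertia scan over candidate cluster numbers
#'
#' Fits [cluster_kmeans()] for each k in `1..k_max` with a shared seed and
#' restart policy and records the inertia (total within-cluster sum of
#' squares), the quantity inspected by the elbow heuristic.
#'
#' @inheritParams cluster_kmeans
#' @param k_max Largest k to scan (default 10, capped at the number of points).
#' @return An `elbow_scan`: tibble with columns `k`, `inertia`.
#' @export
elbow_scan <- function(x, k_max = 10L, seed = 1L, restarts = 10L) {
  x <- as.matrix(x)
  stop_if_not_scalar_count(k_max, "k_max")
  if (k_max > nrow(x)) stop("`k_max` must be <= number of points", call. = FALSE)
  inertia <- vapply(seq_len(k_max), function(k) {
    cluster_kmeans(x, k, seed = seed, restarts = restarts)$inertia
  }, numeric(1))
  out <- tibble::tibble(k = seq_len(k_max), inertia = inertia)
  class(out) <- c("elbow_scan", class(out))
  out
}

#' Elbow point of an inertia scan
#'
#' Formalises the visual elbow heuristic (the point after which inertia
#' decreases roughly linearly). Two formalisations are offered:
#'
#' * `"chord"` (default): the k whose inertia lies farthest below the
#'   straight line joining the first and last points of the scan -- the
#'   point of maximum sag, which tracks what a reader of a scree plot
#'   identifies as the elbow and is robust when the decay spans several
#'   distinct cluster scales.
#' * `"second_diff"`: the k maximising the discrete second difference
#'   `inertia[k-1] - 2*inertia[k] + inertia[k+1]` (the sharpest local
#'   steep-to-flat transition). This variant over-selects k = 2 when a
#'   dominant top-level split coexists with finer structure.
#'
#' Both report an elbow strength (the maximised quantity divided by
#' `inertia[1]`); a perfectly linear decay has strength 0 and is flagged
#' weak, mirroring scans where no elbow is visually decidable.
#'
#' @param scan An `elbow_scan` (>= 3 rows).
#' @param method `"chord"` or `"second_diff"`.
#' @param weak_threshold Strength below which the elbow is flagged weak
#'   (default 0.05).
#' @return An `elbow_choice`: list with `k`, `strength`, `weak`, `method`.
#' @export
elbow_k <- function(scan, method = c("chord", "second_diff"),
                    weak_threshold = 0.05) {
  method <- match.arg(method)
  stopifnot(is.data.frame(scan), all(c("k", "inertia") %in% names(scan)))
  if (nrow(scan) < 3L) stop("elbow detection needs at least 3 k values", call. = FALSE)
  inertia <- scan$inertia[order(scan$k)]
  kk <- sort(scan$k)
  m <- length(inertia)
  if (method == "second_diff") {
    stat <- inertia[1:(m - 2L)] - 2 * inertia[2:(m - 1L)] + inertia[3:m]
    i <- which.max(stat) + 1L
  } else {
    chord <- inertia[1L] + (inertia[m] - inertia[1L]) * (kk - kk[1L]) / (kk[m] - kk[1L])
    stat <- (chord - inertia)[2:(m - 1L)]
    i <- which.max(stat) + 1L
  }
  strength <- if (inertia[1L] > 0) max(stat) / inertia[1L] else 0
  structure(list(k = kk[i], strength = strength,
                 weak = strength < weak_threshold, method = method),
            class = "elbow_choice")
}

#' @export
print.elbow_choice <- function(x, ...) {
  cat("# elbow at k = ", x$k, " (strength ", signif(x$strength, 3),
      if (x$weak) ", weak)" else ")", "\n", sep = "")
  invisible(x)
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance under the permutation
#' (hypergeometric) model and normalised by the larger of the two partition
#' entropies. 1 means identical partitions up to label renaming; values
#' near 0 are expected for independent labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return AMI score (<= 1).
#' @export
ami <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2L) stop("AMI needs at least 2 observations", call. = FALSE)
  ct <- table(labels_a, labels_b)
  a <- rowSums(ct); b <- colSums(ct)
  p <- ct / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (outer(a, b) / n^2)[nz]))
  ent <- function(w) { w <- w[w > 0] / n; -sum(w * log(w)) }
  ha <- ent(a); hb <- ent(b)
  if (ha == 0 && hb == 0) return(1)  # both trivial partitions agree
  emi <- expected_mi(a, b, n)
  denom <- max(ha, hb) - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

# Expected MI under the hypergeometric (permutation) null model.
expected_mi <- function(a, b, n) {
  s <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1)
      s <- s + sum((nij / n) * log(n * nij / (ai * bj)) * exp(lw))
    }
  }
  s
}
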