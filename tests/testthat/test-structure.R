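test_that("scale_features z-scores with the population standard deviation", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1))
  sc <- suppressMessages(scale_features(m))
  expect_equal(sc$values[, "a"], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(sc$values[, "b"], c(0, 0, 0))  # constant-column rule
  expect_equal(sc$n_constant, 1L)

  # idempotence on an already z-scored column
  z <- sc$values[, "a", drop = FALSE]
  expect_equal(suppressMessages(scale_features(z))$values[, 1], unname(z[, 1]),
               tolerance = 1e-9)

  expect_error(scale_features(m[1, , drop = FALSE]), "at least 2 samples")

  mm <- suppressMessages(scale_features(m, method = "minmax"))
  expect_equal(range(mm$values[, "a"]), c(0, 1))
  expect_equal(mm$values[, "b"], c(0, 0, 0))
})

test_that("kmer_pca matches rank, reconstruction and the sign convention", {
  x <- cbind(1:6, 2 * (1:6))  # exactly on the line y = 2x
  p <- kmer_pca(x, n_components = 1)
  expect_equal(p$evr[1], 1)

  withr::with_seed(21, {
    m <- matrix(rnorm(6 * 4), 6, 4)
    full <- kmer_pca(m)
    centered <- sweep(m, 2, colMeans(m))
    expect_equal(full$scores %*% t(full$rotation), centered, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # rotation columns orthonormal
    expect_equal(t(full$rotation) %*% full$rotation, diag(ncol(full$rotation)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(diff(full$evr) <= 1e-12))
    expect_lte(sum(full$evr), 1 + 1e-9)
    # sign convention: largest-|loading| entry positive
    for (j in seq_len(ncol(full$rotation))) {
      expect_gt(full$rotation[which.max(abs(full$rotation[, j])), j], 0)
    }
  })

  expect_error(kmer_pca(x, n_components = 5), "min\\(samples")
})

test_that("kmer_pca agrees with a covariance eigendecomposition oracle", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- sample(4:8, 1); p <- sample(2:5, 1)
      m <- matrix(sample(0:20, n * p, replace = TRUE), n, p)
      fit <- kmer_pca(m)
      centered <- sweep(m, 2, colMeans(m))
      ev <- eigen(crossprod(centered) / n, symmetric = TRUE)
      want_evr <- ev$values / sum(diag(crossprod(centered) / n))
      nc <- ncol(fit$scores)
      expect_equal(fit$evr[1:nc], pmax(want_evr, 0)[1:nc], tolerance = 1e-8)
      # scores match projection onto eigenvectors up to sign
      for (j in seq_len(nc)) {
        if (fit$evr[j] < 1e-10) next
        proj <- centered %*% ev$vectors[, j]
        expect_equal(abs(fit$scores[, j]), abs(drop(proj)), tolerance = 1e-6,
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("select_n_components accumulates explained variance to the target", {
  expect_equal(select_n_components(c(0.5, 0.3, 0.2), 0.8), 2L)
  expect_equal(select_n_components(c(0.9), 0.8), 1L)
  expect_warning(n <- select_n_components(c(0.3, 0.3, 0.3), 0.95), "only")
  expect_equal(n, 3L)
  expect_error(select_n_components(numeric(0)), "empty")
  expect_error(select_n_components(c(0.5), target = 0), "\\(0, 1]")
})

test_that("cluster_kmeans separates well-separated groups deterministically", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  fit <- cluster_kmeans(pts, 2, seed = 1)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
  expect_equal(fit$labels[1], 1L)  # first-appearance canonical labels

  expect_equal(cluster_kmeans(pts, 4, seed = 1)$inertia, 0)
  expect_error(cluster_kmeans(pts, 5, seed = 1), "<= number of points")
  expect_identical(cluster_kmeans(pts, 2, seed = 7), cluster_kmeans(pts, 2, seed = 7))
})

test_that("cluster_kmeans recovers generated Gaussians and sits at a Lloyd fixed point", {
  withr::with_seed(14, {
    centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
    truth <- rep(1:3, each = 4)
    pts <- centers[truth, ] + matrix(rnorm(24, sd = 0.3), 12, 2)
  })
  fit <- cluster_kmeans(pts, 3, seed = 2)
  expect_equal(ami(truth, fit$labels), 1)
  expect_equal(fit$inertia, lloyd_inertia(pts, fit$centers), tolerance = 1e-9)
  # inertia definition: sum of squared distances to assigned center
  expect_equal(fit$inertia,
               sum((pts - fit$centers[fit$labels, ])^2), tolerance = 1e-12)
})

test_that("cluster labels are invariant to sample order after canonical relabeling", {
  withr::with_seed(15, {
    pts <- rbind(matrix(rnorm(10, 0, 0.2), 5, 2),
                 matrix(rnorm(10, 5, 0.2), 5, 2))
    perm <- sample(10)
  })
  a <- cluster_kmeans(pts, 2, seed = 3)
  b <- cluster_kmeans(pts[perm, ], 2, seed = 3)
  expect_equal(ami(a$labels[perm], b$labels), 1)
})

test_that("elbow_scan inertia is non-increasing and has the k = 1 closed form", {
  withr::with_seed(8, pts <- matrix(rnorm(30), 15, 2))
  scan <- elbow_scan(pts, k_max = 6, seed = 4)
  expect_equal(scan$inertia[1],
               sum(sweep(pts, 2, colMeans(pts))^2), tolerance = 1e-9)
  expect_true(all(diff(scan$inertia) <= 1e-8))

  same <- matrix(1, 8, 2)
  expect_equal(elbow_scan(same, k_max = 4, seed = 1)$inertia, rep(0, 4))
  expect_error(elbow_scan(pts, k_max = 30, seed = 1), "<= number of points")
})

test_that("elbow_k finds the sharp elbow and flags linear decays as weak", {
  scan <- tibble::tibble(k = 1:5, inertia = c(100, 20, 18, 17, 16.5))
  # second differences 78, 1, 0.5 -> maximum at k = 2
  sd_choice <- elbow_k(scan, method = "second_diff")
  expect_equal(sd_choice$k, 2L)
  expect_equal(sd_choice$strength, 0.78, tolerance = 1e-9)
  expect_equal(elbow_k(scan, method = "chord")$k, 2L)

  lin <- tibble::tibble(k = 1:6, inertia = seq(60, 10, by = -10))
  for (m in c("chord", "second_diff")) {
    ch <- elbow_k(lin, method = m)
    expect_lt(abs(ch$strength), 1e-12)
    expect_true(ch$weak)
  }
  expect_error(elbow_k(scan[1:2, ]), "at least 3")
})

test_that("elbow drops sharply up to the true cluster number then flattens", {
  withr::with_seed(19, {
    centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
    pts <- centers[rep(1:3, each = 6), ] + matrix(rnorm(36, sd = 0.4), 18, 2)
  })
  scan <- elbow_scan(pts, k_max = 6, seed = 5)
  gaps <- -diff(scan$inertia)
  expect_lt(gaps[3], 0.2 * gaps[2])  # drop after k = 3 is marginal
  expect_equal(elbow_k(scan)$k, 3L)
})

test_that("ami is 1 for identical partitions up to relabeling and symmetric", {
  expect_equal(ami(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(ami(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  a <- c(1, 1, 2, 2, 3, 3, 1, 2)
  b <- c(1, 2, 2, 2, 3, 1, 1, 2)
  expect_equal(ami(a, b), ami(b, a), tolerance = 1e-12)
  expect_lt(ami(a, b), 1)
  expect_error(ami(1:3, 1:4), "equal length")
  expect_equal(ami(rep(1, 5), rep(2, 5)), 1)  # two trivial partitions agree
})

test_that("the expected-MI term matches a Monte-Carlo permutation oracle", {
  withr::with_seed(26, {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    emi <- kmerstruct:::expected_mi(as.vector(table(a)), as.vector(table(b)), 40)
    mc <- mean(vapply(1:2000, function(i) mi_of(a, sample(b)), numeric(1)))
    expect_lt(abs(emi - mc), 0.01)
  })
})

test_that("ami of independent random labelings is near zero", {
  withr::with_seed(27, {
    vals <- vapply(1:300, function(i) {
      ami(sample(0:2, 60, replace = TRUE), sample(0:2, 60, replace = TRUE))
    }, numeric(1))
  })
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("the pipeline recovers three isolated demes end to end", {
  samples <- three_deme_samples(seed = 2)
  fit <- suppressMessages(kmer_structure(samples, k = 9, min_count = 2, seed = 1))
  expect_s3_class(fit, "kmer_structure")
  expect_equal(fit$clusters$K, 3L)
  expect_equal(fit$ami, 1)

  td <- tidy(fit)
  expect_equal(nrow(td), 18L)
  expect_true(all(c("sample_id", "label", "cluster", "PC1", "PC2") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$n_samples, 18L)
  expect_false(g$weak_elbow)
})

test_that("degenerate identical samples give a weak elbow, not an error", {
  seqs <- rep(random_genome(500, seed = 4), 6)
  samples <- tibble::tibble(sample_id = paste0("s", 1:6), sequence = seqs)
  fit <- suppressMessages(suppressWarnings(kmer_structure(samples, k = 5, seed = 1)))
  expect_true(fit$elbow_choice$weak)
  expect_equal(max(abs(fit$scaled$values)), 0)

  expect_error(kmer_structure(samples[1:2, ], k = 5), "at least 3 samples")
  expect_error(kmer_structure(samples, k = 5, n_pcs = 6), "n_pcs")
})

test_that("pipeline PC scores are stable under sample order permutation", {
  samples <- three_deme_samples(seed = 6)
  withr::with_seed(1, perm <- sample(nrow(samples)))
  f1 <- suppressMessages(kmer_structure(samples, k = 7, seed = 2))
  f2 <- suppressMessages(kmer_structure(samples[perm, ], k = 7, seed = 2))
  s1 <- tidy(f1); s2 <- tidy(f2)
  m <- match(s1$sample_id, s2$sample_id)
  for (pc in c("PC1", "PC2")) {
    expect_equal(abs(s1[[pc]]), abs(s2[[pc]][m]), tolerance = 1e-6)
  }
  expect_equal(ami(s1$cluster, s2$cluster[m]), 1)
})

test_that("parameter recovery: well-separated demes give K = 3 and AMI = 1 across seeds", {
  ok <- vapply(1:20, function(sd) {
    s <- three_deme_samples(seed = sd, L = 8000L)
    fit <- suppressMessages(suppressWarnings(
      kmer_structure(s, k = 9, min_count = 1, seed = 1)))
    fit$clusters$K == 3L && isTRUE(all.equal(fit$ami, 1))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("autoplot methods return ggplot objects", {
  samples <- three_deme_samples(seed = 3)
  fit <- suppressMessages(kmer_structure(samples, k = 7, seed = 1))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$elbow), "ggplot")
})
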