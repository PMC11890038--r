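# Independent brute-force oracles, deliberately written with different
# machinery than the package implementation.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

naive_revcomp <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  paste(rev(unname(COMP[chars])), collapse = "")
}

naive_canonical <- function(km) {
  rc <- naive_revcomp(km)
  if (rc < km) rc else km
}

# window-by-window counter with an explicit environment as the hash map
naive_count_kmers <- function(seqs, k, min_count = 1L) {
  env <- new.env(hash = TRUE)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      cw <- naive_canonical(w)
      env[[cw]] <- (env[[cw]] %||% 0L) + 1L
    }
  }
  keys <- ls(env)
  counts <- vapply(keys, function(k2) env[[k2]], integer(1))
  keep <- counts >= min_count
  out <- data.frame(kmer = keys[keep], count = unname(counts[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$kmer, method = "radix"), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

exact_jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Lloyd fixed point started from given centers
lloyd_inertia <- function(x, centers) {
  repeat {
    d <- as.matrix(stats::dist(rbind(centers, x)))[seq_len(nrow(centers)) * -1,
                                                   seq_len(nrow(centers)), drop = FALSE]
    lab <- apply(d, 1L, which.min)
    new_centers <- centers
    for (j in unique(lab)) new_centers[j, ] <- colMeans(x[lab == j, , drop = FALSE])
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  sum((x - centers[lab, , drop = FALSE])^2)
}

# mutual information, for the Monte-Carlo EMI oracle
mi_of <- function(a, b) {
  p <- table(a, b) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

# small, fast, well-separated 3-deme fixture: three isolated demes drifting
# apart from a shared ancestral genome
three_deme_samples <- function(seed = 1, L = 20000L, n_gen = 80L) {
  cfg <- sim_config(genome_length = L, mu = 5e-5, rec = 5e-6,
                    demes = c(4L, 4L, 4L), n_generations = n_gen,
                    samples_per_deme = 6L, base_migration = 0, seed = seed)
  wf_simulate(cfg)
}

# additive distance matrix from a random tree with known path lengths
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
    tr
  })
}
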