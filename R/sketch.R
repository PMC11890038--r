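#' MinHash sketch of a genome
#'
#' Counts canonical k-mers, drops those below `min_count` (the `-m 2`
#' convention: a k-mer must be seen at least twice), hashes each surviving
#' distinct k-mer with a stable seeded 64-bit hash, and keeps the `s`
#' smallest hash values (a bottom-s sketch). Two sketches are comparable
#' only when built with identical `k`, `s`, `min_count` and `hash_seed`.
#'
#' @param x Sequences (character vector or `DNAStringSet`), pooled.
#' @param k K-mer length.
#' @param s Sketch size (number of hash values kept).
#' @param min_count Minimum k-mer count (default 2).
#' @param hash_seed Seed of the hash function (default 42).
#' @param sample_id Optional sample identifier.
#' @return A `minhash_sketch`: list with sorted `hashes`, the parameters,
#'   `sample_id` and `n_kmers` (distinct retained k-mers before truncation).
#' @export
minhash_sketch <- function(x, k, s, min_count = 2L, hash_seed = 42L,
                           sample_id = NA_character_) {
  stop_if_not_scalar_count(s, "s")
  profile <- count_kmers(x, k = k, min_count = min_count, sample_id = sample_id)
  hashes <- if (nrow(profile)) {
    sort(unique(hash_kmers_cpp(profile$kmer, as.double(hash_seed))))
  } else numeric(0)
  if (!length(hashes)) {
    warning("no k-mers survived filtering; sketch is empty", call. = FALSE)
  }
  structure(list(hashes = head(hashes, s), k = as.integer(k),
                 s = as.integer(s), min_count = as.integer(min_count),
                 hash_seed = as.integer(hash_seed), sample_id = sample_id,
                 n_kmers = nrow(profile)),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat("# minhash_sketch: sample ", x$sample_id, ", k = ", x$k, ", s = ", x$s,
      ", ", length(x$hashes), " hashes (", x$n_kmers, " k-mers)\n", sep = "")
  invisible(x)
}

check_sketch_params <- function(a, b) {
  same <- a$k == b$k && a$s == b$s && a$min_count == b$min_count &&
    a$hash_seed == b$hash_seed
  if (!same) stop("sketches were built with different parameters", call. = FALSE)
}

#' Jaccard index estimated from two sketches
#'
#' Mash-style estimator: take the `s` smallest values of the merged hash
#' sets (the union sketch) and return the fraction of them present in both
#' sketches. When `s` is at least the total number of distinct k-mers this
#' equals the exact Jaccard index of the two k-mer sets.
#'
#' @param a,b `minhash_sketch` objects with identical parameters.
#' @return Estimated Jaccard index in \[0, 1\] (`NA` if both are empty).
#' @export
sketch_jaccard <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  check_sketch_params(a, b)
  u <- sort(unique(c(a$hashes, b$hashes)))
  if (!length(u)) {
    warning("both sketches are empty; Jaccard undefined", call. = FALSE)
    return(NA_real_)
  }
  su <- head(u, a$s)
  sum(su %in% a$hashes & su %in% b$hashes) / length(su)
}

#' Mash distance from a Jaccard index
#'
#' `d = -(1/k) * log(2j / (1 + j))`, the mutation-rate-like distance under
#' a simple Poisson model of k-mer survival. `d(1) = 0`; a Jaccard index of
#' 0 (no shared k-mers) saturates at the conventional value 1.
#'
#' @param j Jaccard index (vectorised), in \[0, 1\].
#' @param k K-mer length the index was computed with.
#' @return Mash distance(s).
#' @export
mash_distance <- function(j, k) {
  stop_if_not_scalar_count(k, "k")
  if (any(is.na(j)) || any(j < 0 | j > 1)) {
    stop("`j` must be in [0, 1]", call. = FALSE)
  }
  ifelse(j == 0, 1, -log(2 * j / (1 + j)) / k)
}

#' Pairwise Mash distance matrix
#'
#' @param sketches List of `minhash_sketch` objects (>= 3, identical
#'   parameters).
#' @return Symmetric numeric matrix with zero diagonal, dimnames taken
#'   from the sketches' sample ids.
#' @export
mash_distance_matrix <- function(sketches) {
  if (!is.list(sketches) || length(sketches) < 3L) {
    stop("need at least 3 sketches", call. = FALSE)
  }
  for (i in seq_along(sketches)[-1L]) check_sketch_params(sketches[[1L]], sketches[[i]])
  ids <- vapply(seq_along(sketches), function(i) {
    id <- sketches[[i]]$sample_id
    if (is.na(id)) paste0("sample", i) else id
  }, character(1))
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (jj in (i + 1L):n) {
      d[i, jj] <- d[jj, i] <-
        mash_distance(sketch_jaccard(sketches[[i]], sketches[[jj]]),
                      sketches[[i]]$k)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths,
#' which NJ can produce on noisy matrices, are clamped to zero with a
#' message. The result is an unrooted `phylo` tree, serialisable with
#' [ape::write.tree()].
#'
#' @param d Symmetric numeric matrix (or `dist`) over >= 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3L) {
    stop("`d` must be a square matrix over at least 3 taxa", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tree <- ape::nj(d)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Monophyly of a leaf set on an unrooted tree
#'
#' TRUE iff some edge of the unrooted tree induces the bipartition
#' (`leaves`, complement); singletons and the full leaf set are
#' monophyletic by convention. Symmetric in a set and its complement, as
#' befits unrooted trees.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaves Character vector of tip labels (non-empty subset).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!length(leaves)) stop("`leaves` must be non-empty", call. = FALSE)
  unknown <- setdiff(leaves, tips)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  target <- sort(match(unique(leaves), tips))
  n <- length(tips)
  if (length(target) <= 1L || length(target) == n) return(TRUE)
  comp <- setdiff(seq_len(n), target)
  # tips below each node, accumulated in postorder: every non-root node's
  # descendant tip set is one side of its parent edge's bipartition
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  edges <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  for (node in setdiff(seq_len(n + tree$Nnode), edges[nrow(edges), 1L])) {
    side <- sort(sets[[node]])
    if (identical(side, target) || identical(side, comp)) return(TRUE)
  }
  FALSE
}

#' Monophyly sweep over k-mer length and sketch size
#'
#' For every combination of `ks` and `ss`: sketch all samples, compute the
#' pairwise Mash distance matrix, build the NJ tree and test whether every
#' label group is monophyletic. The resulting grid shows for which
#' parameter choices the sketch distances recover the labeled populations.
#'
#' @param samples Sample table (or manifest path) with `sample_id`,
#'   `label` and `sequence`/`path`; >= 2 labels with >= 2 samples each.
#' @param ks Integer vector of k-mer lengths.
#' @param ss Integer vector of sketch sizes.
#' @param min_count,hash_seed Passed to [minhash_sketch()].
#' @param keep_trees If TRUE, attach the NJ trees as attribute `"trees"`
#'   (named `k<k>_s<s>`).
#' @return A `monophyly_sweep`: tibble with columns `k`, `s`,
#'   `all_monophyletic` and one logical column per label.
#' @export
monophyly_sweep <- function(samples, ks, ss, min_count = 2L, hash_seed = 42L,
                            keep_trees = FALSE) {
  if (is.character(samples) && length(samples) == 1L) {
    samples <- read_manifest(samples)
  }
  labels <- sample_labels(samples)
  if (is.null(labels) || anyNA(labels)) {
    stop("sample table must have a complete `label` column", call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 labels with >= 2 samples each", call. = FALSE)
  }
  seqs <- sample_sequences(samples)
  groups <- split(samples$sample_id, labels)
  trees <- list()
  rows <- list()
  for (k in ks) {
    # hash once per (sample, k); per-s sketches are prefixes of the sorted list
    full <- lapply(samples$sample_id, function(id) {
      minhash_sketch(seqs[[id]], k = k, s = .Machine$integer.max,
                     min_count = min_count, hash_seed = hash_seed,
                     sample_id = id)
    })
    for (s in ss) {
      sk <- lapply(full, function(f) {
        f$hashes <- head(f$hashes, s)
        f$s <- as.integer(s)
        f
      })
      tree <- nj_tree(mash_distance_matrix(sk))
      mono <- vapply(groups, function(g) is_monophyletic(tree, g), logical(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        k = as.integer(k), s = as.integer(s),
        all_monophyletic = all(mono),
        !!!stats::setNames(as.list(mono), names(groups))
      )
      if (keep_trees) trees[[paste0("k", k, "_s", s)]] <- tree
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("monophyly_sweep", class(out))
  if (keep_trees) attr(out, "trees") <- trees
  out
}

#' @rdname autoplot.kmer_structure
#' @export
autoplot.monophyly_sweep <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$s), factor(.data$k),
                                  fill = .data$all_monophyletic)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "sketch size s", y = "k-mer length k",
                  fill = "all groups\nmonophyletic") +
    ggplot2::theme_minimal()
}

#' Serialise a sketch to JSON
#'
#' @param sketch A `minhash_sketch`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_sketch_json <- function(sketch, path) {
  jsonlite::write_json(unclass(sketch), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sketch from JSON
#'
#' @param path JSON file written by [write_sketch_json()].
#' @return A `minhash_sketch`.
#' @export
read_sketch_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hashes <- as.numeric(x$hashes)
  structure(x[c("hashes", "k", "s", "min_count", "hash_seed", "sample_id",
                "n_kmers")],
            class = "minhash_sketch")
}
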