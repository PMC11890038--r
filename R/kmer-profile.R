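#' Reverse complement of DNA sequences
#'
#' Vectorised over its input. Lowercase input is uppercased first; any
#' character outside A/C/G/T is an error naming the offending position.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GATTACA")
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be a character vector", call. = FALSE)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGT]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-ACGT character '", substr(seq[i], bad[i], bad[i]),
         "' at position ", bad[i],
         if (length(seq) > 1L) paste0(" of element ", i), call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, which makes counting strand-independent.
#'
#' @param kmer Character vector of k-mers (A/C/G/T).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("TTT", "CGTA"))
#' @export
canonical_kmer <- function(kmer) {
  rc <- revcomp(kmer)
  kmer <- toupper(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

new_kmer_profile <- function(kmer, count, k, min_count, sample_id = NA_character_) {
  out <- tibble::tibble(kmer = kmer, count = as.integer(count))
  structure(out,
            class = c("kmer_profile", class(out)),
            k = as.integer(k), min_count = as.integer(min_count),
            sample_id = sample_id)
}

#' Count canonical k-mers in a genome
#'
#' Slides a window of width `k` over every record, canonicalises each window
#' and tallies counts. Windows containing any non-ACGT symbol (e.g. `N`) are
#' skipped; soft-masked lowercase is uppercased. Records are pooled into one
#' profile (a genome's chromosomes count together). K-mers rarer than
#' `min_count` are dropped afterwards: by default singletons, which in real
#' assemblies are dominated by sequencing error, are filtered out.
#'
#' @param x Character vector of sequences (or a [Biostrings::DNAStringSet]).
#' @param k K-mer length in bp (1--31).
#' @param min_count Minimum count for a k-mer to be retained (default 2).
#' @param sample_id Optional sample identifier carried in the result.
#' @return A `kmer_profile`: tibble with columns `kmer`, `count`, sorted by
#'   k-mer, with attributes `k`, `min_count`, `sample_id`.
#' @examples
#' count_kmers("ACGTACGT", k = 4, min_count = 1)
#' @export
count_kmers <- function(x, k, min_count = 2L, sample_id = NA_character_) {
  stop_if_not_scalar_count(k, "k")
  if (k > 31L) stop("`k` must be <= 31", call. = FALSE)
  stop_if_not_scalar_count(min_count, "min_count")
  if (inherits(x, "DNAStringSet") || inherits(x, "DNAString")) {
    x <- as.character(x)
  }
  if (!is.character(x)) stop("`x` must be sequences as a character vector", call. = FALSE)
  x <- toupper(x)

  windows <- unlist(lapply(x, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (length(windows)) {
    windows <- windows[grepl("^[ACGT]+$", windows)]
  }
  if (!length(windows)) {
    warning("no valid k-mer windows; returning an empty profile", call. = FALSE)
    return(new_kmer_profile(character(0), integer(0), k, min_count, sample_id))
  }

  uw <- unique(windows)
  canon_u <- canonical_kmer(uw)
  cu <- unique(canon_u)
  counts <- tabulate(match(canon_u, cu)[match(windows, uw)], nbins = length(cu))
  keep <- counts >= min_count
  if (!any(keep)) {
    warning("all k-mers fell below min_count; returning an empty profile",
            call. = FALSE)
  }
  o <- order(cu[keep], method = "radix")
  new_kmer_profile(cu[keep][o], counts[keep][o], k, min_count, sample_id)
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat("# kmer_profile: sample ", attr(x, "sample_id") %||% NA,
      ", k = ", attr(x, "k"),
      ", min_count = ", attr(x, "min_count"),
      ", ", nrow(x), " k-mers\n", sep = "")
  NextMethod()
}

#' K-mer frequency spectrum of a profile
#'
#' Tallies how many distinct k-mers occur at each count. Examining this
#' spectrum (looking for a roughly symmetric unimodal shape) is how a
#' suitable k-mer size is chosen for a given genome size.
#'
#' @param profile A `kmer_profile` (or any tibble with `kmer`, `count`).
#' @return Tibble with columns `count`, `n_kmers`, sorted by count.
#' @export
kmer_spectrum <- function(profile) {
  stopifnot(is.data.frame(profile), "count" %in% names(profile))
  if (nrow(profile) == 0L) {
    return(tibble::tibble(count = integer(0), n_kmers = integer(0)))
  }
  tab <- table(profile$count)
  tibble::tibble(count = as.integer(names(tab)), n_kmers = as.integer(tab))
}

#' Count profiles for a table of samples
#'
#' @param samples Data frame with `sample_id` and either `sequence` (in-memory
#'   genomes) or `path` (FASTA files, plain or gzip).
#' @inheritParams count_kmers
#' @return Named list of `kmer_profile` objects, one per sample.
#' @export
kmer_profiles <- function(samples, k, min_count = 2L) {
  seqs <- sample_sequences(samples)
  out <- lapply(names(seqs), function(id) {
    count_kmers(seqs[[id]], k = k, min_count = min_count, sample_id = id)
  })
  names(out) <- names(seqs)
  out
}

#' K-mers shared by every profile
#'
#' Exact intersection of the (already min-count-filtered) key sets of all
#' profiles. Because filtering happens before intersecting, every retained
#' k-mer has a trustworthy count of at least `min_count` in every sample:
#' keeping k-mers that are singletons somewhere would force an arbitrary
#' 0-or-1 call for those samples.
#'
#' @param profiles List of `kmer_profile` objects with identical `k`.
#' @return Character vector of shared k-mers, sorted ascending.
#' @export
shared_kmers <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    stop("need at least two profiles", call. = FALSE)
  }
  ks <- vapply(profiles, function(p) attr(p, "k") %||% NA_integer_, integer(1))
  if (length(unique(ks)) != 1L || anyNA(ks)) {
    stop("profiles have mixed k: ", paste(unique(ks), collapse = ", "), call. = FALSE)
  }
  common <- Reduce(intersect, lapply(profiles, function(p) p$kmer))
  if (!length(common)) {
    warning("no k-mers are shared by all samples", call. = FALSE)
  }
  sort_c(common)
}

#' Sample-by-feature matrix of shared k-mer counts
#'
#' Assembles the PCA input: one row per sample, one column per shared k-mer,
#' entries are the per-sample counts. Row order follows the profile list.
#'
#' @param profiles List of `kmer_profile` objects.
#' @param features Sorted character vector of k-mers; defaults to
#'   [shared_kmers()] of the profiles. Every feature must be present in every
#'   profile.
#' @return A `kmer_matrix`: integer matrix (samples x features) with sample
#'   ids as rownames, plus attributes `k` and `min_count`.
#' @export
kmer_count_matrix <- function(profiles, features = NULL) {
  if (is.null(features)) features <- shared_kmers(profiles)
  ids <- vapply(seq_along(profiles), function(i) {
    attr(profiles[[i]], "sample_id") %||% names(profiles)[i] %||% paste0("sample", i)
  }, character(1))
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    idx <- match(features, p$kmer)
    if (anyNA(idx)) {
      stop("k-mer '", features[which(is.na(idx))[1L]],
           "' is missing from sample '", ids[i], "'", call. = FALSE)
    }
    p$count[idx]
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(integer(0), nrow = 0, ncol = length(features))
  dimnames(m) <- list(ids, features)
  structure(m,
            k = attr(profiles[[1L]], "k"),
            min_count = attr(profiles[[1L]], "min_count"),
            class = c("kmer_matrix", class(m)))
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("# kmer_matrix: ", nrow(x), " samples x ", ncol(x),
      " shared k-mers (k = ", attr(x, "k"), ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy.kmer_structure
#' @export
tidy.kmer_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "k") <- NULL
  attr(m, "min_count") <- NULL
  tibble::as_tibble(m, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "kmer", values_to = "count")
}
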