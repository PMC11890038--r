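#' Read a genome FASTA file
#'
#' @param path FASTA file, plain or gzip-compressed.
#' @return Character vector of record sequences (names = record ids).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  out
}

#' Read a sample manifest
#'
#' A manifest is a TSV with columns `sample_id`, `path` and optionally
#' `label`; relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV file.
#' @return Tibble with columns `sample_id`, `path` and, if present, `label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns sample_id and path", call. = FALSE)
  }
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Write a k-mer profile as TSV
#'
#' @param profile A `kmer_profile`.
#' @param path Output file (columns `kmer`, `count`).
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile)[c("kmer", "count")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a k-mer profile TSV
#'
#' @param path TSV with columns `kmer`, `count`.
#' @param min_count Filter applied when the profile was built (metadata only).
#' @param sample_id Optional sample id to attach.
#' @return A `kmer_profile`.
#' @export
read_profile_tsv <- function(path, min_count = 2L, sample_id = NA_character_) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  k <- if (nrow(x)) nchar(x$kmer[1L]) else NA_integer_
  new_kmer_profile(x$kmer, x$count, k, min_count, sample_id)
}

#' Write a k-mer count matrix as TSV
#'
#' First column `sample_id`, remaining columns one per k-mer.
#'
#' @param x A `kmer_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kmer_matrix_tsv <- function(x, path) {
  m <- unclass(x)
  attr(m, "k") <- NULL
  attr(m, "min_count") <- NULL
  readr::write_tsv(tibble::as_tibble(m, rownames = "sample_id"), path,
                   progress = FALSE)
  invisible(path)
}

#' Write simulated genomes as FASTA files plus a manifest
#'
#' One uppercase, 80-column-wrapped FASTA per sample, plus `manifest.tsv`
#' (columns `sample_id`, `path`, `label`) in `out_dir`.
#'
#' @param samples Sample table with `sample_id`, `sequence` and `label`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly; the manifest tibble is
#'   attached as attribute `"manifest"`.
#' @export
write_genomes <- function(samples, out_dir) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "sequence") %in% names(samples)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  paths <- file.path(out_dir, paste0(samples$sample_id, ".fasta"))
  for (i in seq_len(nrow(samples))) {
    dna <- Biostrings::DNAStringSet(toupper(samples$sequence[i]))
    names(dna) <- samples$sample_id[i]
    Biostrings::writeXStringSet(dna, paths[i], width = 80L)
  }
  manifest <- tibble::tibble(
    sample_id = samples$sample_id,
    path = basename(paths),
    label = if ("label" %in% names(samples)) samples$label else NA_character_
  )
  mpath <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, mpath, progress = FALSE)
  structure(invisible(mpath), manifest = manifest)
}
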