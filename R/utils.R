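# C-locale lexicographic sort, independent of the session collation
sort_c <- function(x) sort(x, method = "radix")

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
}

# Sequences for a sample table: either an in-memory `sequence` column or a
# `path` column pointing at FASTA files (plain or gzip). Returns a named
# list of character vectors (one element per sample, one string per record).
sample_sequences <- function(samples) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  if ("sequence" %in% names(samples)) {
    seqs <- as.list(samples$sequence)
  } else if ("path" %in% names(samples)) {
    seqs <- lapply(samples$path, read_genome_fasta)
  } else {
    stop("sample table needs a `sequence` or `path` column", call. = FALSE)
  }
  names(seqs) <- samples$sample_id
  seqs
}

sample_labels <- function(samples) {
  if ("label" %in% names(samples)) as.character(samples$label) else NULL
}
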