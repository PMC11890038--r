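#' Random ancestral genome
#'
#' I.i.d. uniform bases over A/C/G/T.
#'
#' @param length Genome length in bp (>= 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed = NULL) {
  stop_if_not_scalar_count(length, "length")
  draw <- function() paste(c("A", "C", "G", "T")[sample.int(4L, length, replace = TRUE)],
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# ---- demographic events -----------------------------------------------------

#' Demographic events for the Wright-Fisher simulator
#'
#' Events fire at the start of their generation. `ev_split()` founds a new
#' deme whose first offspring generation draws its parents from
#' `source`; `ev_admix_found()` founds a deme whose founding parents come
#' from several `sources` with the given `proportions` (one generation of
#' admixture, after which the deme reproduces from itself unless migration
#' says otherwise). `ev_migration()` installs an explicit migration matrix
#' `m` where `m[d, j]` is the probability that an offspring born in deme
#' `d` has its parents drawn from deme `j` (rows may sum to at most 1; the
#' remainder is within-deme reproduction). `ev_growth()` starts exponential
#' growth of a deme at `rate` per generation, capped at `cap_factor` times
#' the size at onset.
#'
#' @param generation Generation at which the event fires (1-based).
#' @param deme,source Deme index.
#' @param new_size New effective size N (the deme holds 2N haplotypes).
#' @param sources,proportions Source demes and their founding proportions
#'   (must sum to 1).
#' @param m Square migration matrix over the demes extant at `generation`.
#' @param rate Per-generation growth rate (> 0).
#' @param cap_factor Growth cap as a multiple of the size at onset.
#' @return An event object (a classed list).
#' @name sim-events
NULL

#' @rdname sim-events
#' @export
ev_size_change <- function(generation, deme, new_size) {
  structure(list(type = "size_change", generation = as.integer(generation),
                 deme = as.integer(deme), new_size = as.integer(new_size)),
            class = "wf_event")
}

#' @rdname sim-events
#' @export
ev_split <- function(generation, source, new_size) {
  structure(list(type = "split", generation = as.integer(generation),
                 source = as.integer(source), new_size = as.integer(new_size)),
            class = "wf_event")
}

#' @rdname sim-events
#' @export
ev_admix_found <- function(generation, sources, proportions, new_size) {
  if (length(sources) != length(proportions) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("founding proportions must match sources and sum to 1", call. = FALSE)
  }
  structure(list(type = "admix_found", generation = as.integer(generation),
                 sources = as.integer(sources), proportions = proportions,
                 new_size = as.integer(new_size)),
            class = "wf_event")
}

#' @rdname sim-events
#' @export
ev_migration <- function(generation, m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || any(m < 0) || any(rowSums(m) - diag(m) > 1 + 1e-9)) {
    stop("migration matrix must be square, non-negative, off-diagonal row sums <= 1",
         call. = FALSE)
  }
  diag(m) <- 0
  structure(list(type = "migration", generation = as.integer(generation), m = m),
            class = "wf_event")
}

#' @rdname sim-events
#' @export
ev_growth <- function(generation, deme, rate, cap_factor = 10) {
  if (!is.numeric(rate) || rate <= 0) stop("growth rate must be > 0", call. = FALSE)
  structure(list(type = "growth", generation = as.integer(generation),
                 deme = as.integer(deme), rate = rate, cap_factor = cap_factor),
            class = "wf_event")
}

# ---- configuration ----------------------------------------------------------

#' Wright-Fisher simulation configuration
#'
#' Demes of effective size N are populated by 2N haploid haplotypes (the
#' diploid genome count), which keeps sequence emission simple while
#' matching the usual effective-size bookkeeping; "six genomes per
#' population" means six haplotypes. Mutation is neutral and finite-sites
#' (a site can mutate repeatedly; later mutations overwrite), recombination
#' places a Poisson number of crossovers uniformly along the genome.
#'
#' @param genome_length Genome length in bp.
#' @param mu Per-site per-generation mutation rate.
#' @param rec Per-site per-generation recombination rate.
#' @param demes Integer vector of initial effective deme sizes.
#' @param events List of events built with the `ev_*()` constructors.
#' @param n_generations Number of generations to simulate.
#' @param samples_per_deme Haplotypes sampled per deme at the end (default 6).
#' @param base_migration Default symmetric per-offspring migration
#'   probability between extant demes, used whenever no explicit
#'   [ev_migration()] matrix is active (default 0).
#' @param seed Integer seed; the whole run is deterministic given the config.
#' @return A `sim_config`.
#' @export
sim_config <- function(genome_length, mu, rec, demes, events = list(),
                       n_generations, samples_per_deme = 6L,
                       base_migration = 0, seed = 1L) {
  stop_if_not_scalar_count(genome_length, "genome_length")
  stop_if_not_scalar_count(n_generations, "n_generations", min = 0L)
  stop_if_not_scalar_count(samples_per_deme, "samples_per_deme")
  if (any(c(mu, rec) < 0) || any(c(mu, rec) > 1)) {
    stop("`mu` and `rec` must be rates in [0, 1]", call. = FALSE)
  }
  if (base_migration < 0 || base_migration >= 1) {
    stop("`base_migration` must be in [0, 1)", call. = FALSE)
  }
  demes <- as.integer(demes)
  if (!length(demes) || any(demes < 1L)) {
    stop("`demes` must be positive initial sizes", call. = FALSE)
  }
  gens <- vapply(events, function(e) e$generation, integer(1))
  events <- events[order(gens)]
  cfg <- structure(list(genome_length = as.integer(genome_length), mu = mu,
                        rec = rec, demes = demes, events = events,
                        n_generations = as.integer(n_generations),
                        samples_per_deme = as.integer(samples_per_deme),
                        base_migration = base_migration,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  n_demes <- length(cfg$demes)
  for (ev in cfg$events) {
    if (ev$generation < 1L || ev$generation > cfg$n_generations) {
      stop("event at generation ", ev$generation,
           " is outside 1..n_generations", call. = FALSE)
    }
    refs <- switch(ev$type,
                   size_change = ev$deme, split = ev$source,
                   admix_found = ev$sources, growth = ev$deme,
                   migration = seq_len(nrow(ev$m)))
    if (any(refs > n_demes) || (ev$type == "migration" && nrow(ev$m) != n_demes)) {
      stop("event at generation ", ev$generation,
           " references deme(s) not extant at that time", call. = FALSE)
    }
    if (ev$type %in% c("split", "admix_found")) n_demes <- n_demes + 1L
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("# sim_config: L = ", x$genome_length, " bp, mu = ", x$mu,
      ", rec = ", x$rec, "\n  demes N = (", paste(x$demes, collapse = ", "),
      "), ", length(x$events), " events, ", x$n_generations,
      " generations, ", x$samples_per_deme, " samples/deme, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# ---- engine -----------------------------------------------------------------

# A haplotype is a sparse set of derived sites over the ancestral genome:
# parallel vectors pos (1..L) and base (1..4), no duplicate positions.

empty_haplotype <- function() list(pos = integer(0), base = integer(0))

recombine_haps <- function(h1, h2, breakpoints) {
  if (!length(breakpoints)) return(h1)
  bp <- sort(breakpoints)
  keep1 <- findInterval(h1$pos, bp) %% 2L == 0L
  keep2 <- findInterval(h2$pos, bp) %% 2L == 1L
  list(pos = c(h1$pos[keep1], h2$pos[keep2]),
       base = c(h1$base[keep1], h2$base[keep2]))
}

mutate_hap <- function(h, positions, ancestral) {
  for (p in positions) {
    i <- match(p, h$pos)
    cur <- if (is.na(i)) ancestral[p] else h$base[i]
    nb <- sample.int(4L, 1L)
    if (nb == cur) nb <- nb %% 4L + 1L  # uniform over the 3 other bases
    if (is.na(i)) {
      h$pos <- c(h$pos, p)
      h$base <- c(h$base, nb)
    } else {
      h$base[i] <- nb
    }
  }
  h
}

# One generation of reproduction for every deme. `sources[[d]]` optionally
# overrides the parental deme distribution (founding generation).
wf_reproduce <- function(demes, target_sizes, mig, sources, mu, rec, L,
                         ancestral, gen) {
  n_demes <- length(target_sizes)
  ev_mut <- mu * L
  ev_rec <- rec * L
  out <- vector("list", n_demes)
  for (d in seq_len(n_demes)) {
    n_off <- 2L * target_sizes[d]
    if (n_off < 2L) stop("deme ", d, " collapsed at generation ", gen, call. = FALSE)
    if (!is.null(sources[[d]])) {
      src_demes <- sources[[d]]$sources
      src_probs <- sources[[d]]$proportions
    } else {
      row <- mig[d, ]
      # a deme founded this generation has no parental pool yet
      row[vapply(demes, function(p) length(p) < 2L, logical(1))] <- 0
      others <- setdiff(seq_len(n_demes), d)
      src_demes <- c(d, others)
      src_probs <- c(1 - sum(row[others]), row[others])
    }
    src_of <- if (length(src_demes) == 1L) rep(src_demes, n_off) else
      sample(src_demes, n_off, replace = TRUE, prob = src_probs)
    kids <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      pool <- demes[[src_of[i]]]
      pr <- sample.int(length(pool), 2L)
      child <- demes[[src_of[i]]][[pr[1L]]]
      nx <- rpois(1L, ev_rec)
      if (nx > 0L) {
        child <- recombine_haps(child, pool[[pr[2L]]], sample.int(L, nx, replace = TRUE))
      }
      nm <- rpois(1L, ev_mut)
      if (nm > 0L) {
        child <- mutate_hap(child, sample.int(L, nm, replace = TRUE), ancestral)
      }
      kids[[i]] <- child
    }
    out[[d]] <- kids
  }
  out
}

materialize_hap <- function(h, ancestral) {
  s <- ancestral
  if (length(h$pos)) s[h$pos] <- h$base
  paste(c("A", "C", "G", "T")[s], collapse = "")
}

#' Run a forward-time Wright-Fisher simulation
#'
#' Simulates the configured demography generation by generation and, at the
#' end, samples `samples_per_deme` haplotypes uniformly without replacement
#' from each extant deme, materialising their full sequences over the
#' random ancestral genome.
#'
#' @param config A [sim_config()] (or [scenario_config()]) object.
#' @return A sample table: tibble with columns `sample_id` (e.g.
#'   `pop1_s0`), `label` (deme, e.g. `pop1`) and `sequence`; the config is
#'   attached as attribute `"config"`.
#' @export
wf_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    L <- config$genome_length
    ancestral <- sample.int(4L, L, replace = TRUE)
    sizes <- config$demes
    demes <- lapply(sizes, function(N) rep(list(empty_haplotype()), 2L * N))
    growth <- vector("list", length(sizes))
    mig_override <- NULL
    ev_by_gen <- split(config$events,
                       vapply(config$events, function(e) e$generation, integer(1)))

    for (gen in seq_len(config$n_generations)) {
      founding <- vector("list", length(sizes))
      for (ev in ev_by_gen[[as.character(gen)]] %||% list()) {
        if (ev$type == "size_change") {
          sizes[ev$deme] <- ev$new_size
        } else if (ev$type == "split") {
          sizes <- c(sizes, ev$new_size)
          demes <- c(demes, list(list()))
          growth <- c(growth, list(NULL))
          founding <- c(founding, list(list(sources = ev$source, proportions = 1)))
          mig_override <- NULL
        } else if (ev$type == "admix_found") {
          sizes <- c(sizes, ev$new_size)
          demes <- c(demes, list(list()))
          growth <- c(growth, list(NULL))
          founding <- c(founding,
                        list(list(sources = ev$sources, proportions = ev$proportions)))
          mig_override <- NULL
        } else if (ev$type == "migration") {
          mig_override <- ev$m
        } else if (ev$type == "growth") {
          growth[[ev$deme]] <- list(rate = ev$rate,
                                    cap = ceiling(ev$cap_factor * sizes[ev$deme]))
        }
      }
      for (d in seq_along(sizes)) {
        if (!is.null(growth[[d]])) {
          sizes[d] <- min(growth[[d]]$cap,
                          max(sizes[d] + 1L, round(sizes[d] * (1 + growth[[d]]$rate))))
        }
      }
      if (any(sizes < 1L)) {
        stop("deme size reached 0 at generation ", gen, call. = FALSE)
      }
      mig <- mig_override %||% {
        m <- matrix(config$base_migration, length(sizes), length(sizes))
        diag(m) <- 0
        m
      }
      demes <- wf_reproduce(demes, sizes, mig, founding,
                            config$mu, config$rec, L, ancestral, gen)
    }

    recs <- lapply(seq_along(demes), function(d) {
      pool <- demes[[d]]
      if (length(pool) < config$samples_per_deme) {
        stop("deme ", d, " has only ", length(pool), " haplotypes; cannot sample ",
             config$samples_per_deme, call. = FALSE)
      }
      idx <- sample.int(length(pool), config$samples_per_deme)
      tibble::tibble(
        sample_id = paste0("pop", d, "_s", seq_len(config$samples_per_deme) - 1L),
        label = paste0("pop", d),
        sequence = vapply(pool[idx], materialize_hap, character(1), ancestral)
      )
    })
    out <- dplyr::bind_rows(recs)
    attr(out, "config") <- config
    out
  })
}

#' Pairwise sequence divergence of a sample set
#'
#' Per-site Hamming differences between all sample pairs; useful for
#' checking simulator calibration against the coalescent expectation
#' E\[pi\] = theta.
#'
#' @param samples Sample table with `sample_id`, `sequence` and optionally
#'   `label`.
#' @return Tibble with one row per unordered pair: `sample_i`, `sample_j`,
#'   `label_i`, `label_j`, `diff_per_site`.
#' @export
pairwise_divergence <- function(samples) {
  stopifnot(is.data.frame(samples), "sequence" %in% names(samples))
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  chars <- do.call(rbind, strsplit(samples$sequence, ""))
  L <- ncol(chars)
  lab <- sample_labels(samples) %||% rep(NA_character_, n)
  pairs <- utils::combn(n, 2L)
  tibble::tibble(
    sample_i = samples$sample_id[pairs[1L, ]],
    sample_j = samples$sample_id[pairs[2L, ]],
    label_i = lab[pairs[1L, ]],
    label_j = lab[pairs[2L, ]],
    diff_per_site = vapply(seq_len(ncol(pairs)), function(p) {
      sum(chars[pairs[1L, p], ] != chars[pairs[2L, p], ]) / L
    }, numeric(1))
  )
}
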