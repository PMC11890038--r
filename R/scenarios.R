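#' Demographic scenario library
#'
#' Named demographic scenarios used to validate the k-mer structure
#' pipeline, each a multi-deme Wright-Fisher history at a nominal scale of
#' a 10 Mb genome, mutation rate 1e-7, recombination rate 1e-8 and an
#' initial deme of effective size 500:
#'
#' * `"three-pop"`: the founding deme grows to 1,000 at generation 2,000; a
#'   second deme of 180 splits off at generation 3,500 and a third deme of
#'   180 splits from the second at generation 4,500 (out-of-Africa-style
#'   topology); minimal symmetric migration; sampling at generation 7,000.
#' * `"three-pop-early"`: as above, sampled at generation 5,500.
#' * `"three-pop-growth"`: as `"three-pop"` with exponential growth of
#'   demes 2 and 3 from generation 4,500 (rate `growth_rate` per
#'   generation, capped at 10x the size at onset).
#' * `"four-pop-admix"`: as `"three-pop"` plus a fourth deme of 180 founded
#'   at generation 5,500 with equal parentage from demes 2 and 3 for a
#'   single generation, then isolated (no migration to or from it).
#' * `"hybrid-migration"`: three demes of sizes 500, 500 and 200 from the
#'   start; the small deme draws all its parents equally from the two
#'   large demes for the first 10 generations, after which symmetric
#'   migration at rate `migration` (default 0.02%) connects the small deme
#'   with each large one; sampling at generation 5,500.
#'
#' Rescaling with `scale` < 1 multiplies genome length, deme sizes and
#' generation counts by `scale` and divides the per-site rates (mutation,
#' recombination) by `scale`, preserving the population-scaled parameters
#' theta and rho; the exponential growth rate is likewise divided by
#' `scale` so the relative size trajectory is preserved. Per-offspring
#' migration probabilities stay at their nominal values: the chance that a
#' sampled haplotype is a recent migrant is governed by the per-individual
#' rate, which is what these scenarios probe. Scaled deme sizes are
#' floored so each deme holds at least `samples_per_deme` haplotypes, and
#' migration rates are capped at 0.45 per source (row sums <= 0.9). The attached
#' attribute `"k"` records the k-mer size whose count distribution is
#' symmetric at the nominal genome size (9 for the three/four-population
#' scenarios, 11 for `"hybrid-migration"`).
#'
#' @param name Scenario name (see above); unknown names raise an error
#'   listing the valid ones.
#' @param scale Rescaling factor in (0, 1].
#' @param samples_per_deme Haplotypes sampled per deme (default 6).
#' @param seed Integer seed stored in the config.
#' @param migration Post-founding migration rate for `"hybrid-migration"`
#'   at nominal scale (default 2e-4, i.e. 0.02%).
#' @param growth_rate Nominal per-generation growth rate for
#'   `"three-pop-growth"` (default 0.005).
#' @param base_migration Nominal "minimal migration" between demes of the
#'   three/four-population scenarios (default 1e-4).
#' @return A [sim_config()] with attributes `"name"`, `"scale"` and `"k"`.
#' @examples
#' scenario_config("three-pop", scale = 0.01)
#' @export
scenario_config <- function(name, scale = 1, samples_per_deme = 6L, seed = 1L,
                            migration = 2e-4, growth_rate = 0.005,
                            base_migration = 1e-4) {
  valid <- c("three-pop", "three-pop-early", "three-pop-growth",
             "four-pop-admix", "hybrid-migration")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("unknown scenario; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1) {
    stop("`scale` must be in (0, 1]", call. = FALSE)
  }
  sgen <- function(g) max(1L, as.integer(round(g * scale)))
  ssize <- function(N) max(ceiling(samples_per_deme / 2), as.integer(round(N * scale)))
  # migration rates are per offspring and stay nominal under rescaling: the
  # chance that a *sampled* haplotype is a recent migrant scales with the
  # per-individual rate, and that is the quantity the scenarios are about
  srate <- function(r) min(r, 0.45)

  L <- as.integer(round(1e7 * scale))
  mu <- 1e-7 / scale
  rec <- 1e-8 / scale

  if (name == "hybrid-migration") {
    f_end <- sgen(10)
    n_gen <- sgen(5500)
    m_found <- matrix(0, 3, 3)
    m_found[3, 1] <- m_found[3, 2] <- 0.5  # founding proportions, not scaled
    m_post <- matrix(0, 3, 3)
    m <- srate(migration)
    m_post[3, 1] <- m_post[3, 2] <- m_post[1, 3] <- m_post[2, 3] <- m
    cfg <- sim_config(
      genome_length = L, mu = mu, rec = rec,
      demes = c(ssize(500), ssize(500), ssize(200)),
      events = list(ev_migration(1L, m_found),
                    ev_migration(min(f_end + 1L, n_gen), m_post)),
      n_generations = n_gen, samples_per_deme = samples_per_deme,
      base_migration = 0, seed = seed
    )
    k_rec <- 11L
  } else {
    events <- list(
      ev_size_change(sgen(2000), 1L, ssize(1000)),
      ev_split(sgen(3500), 1L, ssize(180)),
      ev_split(sgen(4500), 2L, ssize(180))
    )
    n_gen <- if (name == "three-pop-early") sgen(5500) else sgen(7000)
    if (name == "three-pop-growth") {
      g <- min(growth_rate / scale, 1)
      events <- c(events, list(ev_growth(sgen(4500), 2L, g),
                               ev_growth(sgen(4500), 3L, g)))
    }
    if (name == "four-pop-admix") {
      m_iso <- matrix(srate(base_migration), 4, 4)
      m_iso[4, ] <- m_iso[, 4] <- 0
      diag(m_iso) <- 0
      events <- c(events, list(
        ev_admix_found(sgen(5500), sources = c(2L, 3L),
                       proportions = c(0.5, 0.5), new_size = ssize(180)),
        ev_migration(sgen(5500) + 1L, m_iso)
      ))
    }
    cfg <- sim_config(
      genome_length = L, mu = mu, rec = rec, demes = ssize(500),
      events = events, n_generations = n_gen,
      samples_per_deme = samples_per_deme,
      base_migration = srate(base_migration), seed = seed
    )
    k_rec <- 9L
  }
  attr(cfg, "name") <- name
  attr(cfg, "scale") <- scale
  attr(cfg, "k") <- k_rec
  cfg
}
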