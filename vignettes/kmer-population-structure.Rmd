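---
title: "Population structure from canonical k-mer frequencies: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure from canonical k-mer frequencies: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`kmerstruct` infers population structure from genome sequences without
alignment, variant calling or marker selection. Each genome is summarised
by its profile of **canonical k-mer frequencies**: every length-k window is
replaced by the lexicographically smaller of itself and its reverse
complement (so counting is strand-independent), and the counts over all
windows form the sample's summary statistic. Population structure is then
read off the samples-by-k-mers count matrix with standard multivariate
machinery:

1. **Filtering.** K-mers with per-sample count below `min_count` (default
   2) are dropped. In real assemblies singletons are dominated by
   sequencing error; dropping them *before* intersecting also avoids
   having to decide between a count of 0 and 1 for a k-mer that is a
   singleton in some samples.
2. **Intersection.** Only k-mers present (post-filter) in *every* sample
   are kept, giving a complete rectangular count matrix.
3. **Standardization.** Each feature is z-scored with the population
   standard deviation. Without this, high-count k-mers dominate the
   principal axes.
4. **PCA.** Scores, loadings and explained variance ratios come from the
   SVD of the centered matrix.
5. **K-means + elbow.** K-means (k-means++ initialisation, 10 restarts,
   seeded) is run for k = 1..10 on the first two principal components;
   the inertia scree determines the cluster number K; the final clustering
   at K gives the inferred populations.
6. **Scoring.** When true labels are known, agreement is measured with
   adjusted mutual information (AMI): chance-corrected under the
   permutation model, normalised by the larger partition entropy, 1 iff
   the partitions agree up to relabeling.

```r
library(kmerstruct)
cfg <- scenario_config("three-pop", scale = 0.01, seed = 1)
fit <- wf_simulate(cfg) |> kmer_structure(k = 9, seed = 1)
glance(fit)
autoplot(fit)
```

## Parameters that matter

* `k` (k-mer length, bp). Too short and every k-mer occurs everywhere
  (uninformative); too long and most k-mers are unique (everything is
  filtered). A good k gives a roughly symmetric unimodal count spectrum
  (`kmer_spectrum()`): for ~3 Gb human genomes that is k = 21; for the
  10 Mb simulated genomes k = 9, and k = 11 for the hybrid-migration
  simulations. At the package's test scale (100 kb genomes) the same k
  values are used so the feature space matches the scenario definitions.
* `min_count` (default 2). The singleton filter. For simulated genomes
  without sequencing error it mainly trims the sparse tail of the
  spectrum; setting 1 is reasonable for small error-free fixtures.
* `n_pcs` (default 2). Clustering uses the two leading PCs. The variance
  of a k-mer matrix tends to spread thinly across components; feeding all
  components up to 80% cumulative variance into K-means typically leaves
  the inertia scree with no usable elbow, while the two leading components
  give stable clusters. The 80%-cumulative alternative remains available
  (`cluster_on = "cumvar"`), and `glance()` reports how many components
  reach the target.
* `seed`. K-means restarts are the only stochastic step of the analysis
  pipeline; a fixed seed makes runs exactly reproducible.

## Choosing the number of clusters

The elbow heuristic is visual in origin; `elbow_k()` offers two
formalisations and reports an *elbow strength* so that undecidable screes
can be flagged (`weak = TRUE` when strength < 0.05; a perfectly linear
decay has strength 0).

* `"chord"` (default): the k whose inertia sags farthest below the
  straight line joining the two ends of the scan. This matches what a
  reader of a scree plot picks out, and behaves well when a dominant
  top-level split (one population far from the rest) coexists with finer
  structure.
* `"second_diff"`: the k maximising the discrete second difference of the
  inertia. This is the more literal "sharpest local bend", but on
  hierarchically structured data the enormous drop from k = 1 to k = 2
  dominates the statistic and k = 2 is over-selected. In side-by-side runs
  over the simulated scenario families the chord method reproduced the
  expected cluster numbers markedly more often, which is why it is the
  default; the scenario suite in `tests/testthat/test-acceptance.R` and
  `scripts/acceptance.R` measures the recovery rates.

## The simulator

`wf_simulate()` is a forward-time multi-deme Wright-Fisher simulator. A
deme of "effective size N" holds 2N haploid haplotypes (the diploid genome
count), and a sampled "genome" is one haplotype; this keeps sequence
emission trivial while preserving the usual effective-size bookkeeping.
Each offspring draws a parental deme (its own, or another with the
per-offspring probabilities of the migration matrix row), draws two parent
haplotypes without replacement, recombines them with a
Poisson(rec x L) number of uniformly placed crossovers (alternating
parental segments), and receives Poisson(mu x L) new mutations at uniform
positions, each changing the site to a uniformly chosen different base.
Mutation is finite-sites: a site can mutate repeatedly and later mutations
overwrite. Haplotypes are stored as sparse derived-site maps over the
random ancestral genome and materialised only at sampling, so memory stays
proportional to segregating variation.

Demographic events (size changes, splits, admixture foundings, migration
matrix changes, exponential growth) fire at the start of their generation.
A split deme draws its founding generation's parents from the source deme;
an admixture-founded deme draws each founder's parental deme from the
configured proportions for exactly one generation.

`scenario_config()` provides the scenario library: a three-population
out-of-Africa-style history (founding deme of 500 growing to 1,000 at
generation 2,000; deme 2 of 180 splitting at 3,500; deme 3 of 180
splitting from deme 2 at 4,500; sampling 6 genomes per deme at 7,000, or
5,500 in the early-sampling variant), an exponential-growth variant
(growth of demes 2 and 3 from generation 4,500 at 0.5%/generation, capped
at 10x the size at onset), a four-population variant with an
admixture-founded then isolated deme, and a hybrid-migration design (demes
of 500/500/200 where the small deme is founded by ten generations of equal
origin from the two large demes, then connected to them by symmetric
migration, 0.02% by default). Where the underlying recipes leave details
open -- the split topology, the growth rate, the founding generation of
the admixed deme, the "minimal" background migration (default 1e-4 per
offspring per generation) -- the library fixes the values above and they
are deliberately configurable.

### Rescaling

Scenarios are defined at a nominal 10 Mb scale but are routinely run at
`scale = 0.01` (100 kb, ~70 generations), where a full pipeline run takes
seconds. Rescaling multiplies genome length, deme sizes and generation
counts by `scale` and divides the per-site rates mu and rec by `scale`:
the population-scaled parameters theta = 2(2N)mu and rho are preserved, so
expected diversity levels match the nominal scenario. The exponential
growth *rate* is also divided by `scale` so the relative size trajectory
over the (shortened) growth epoch is preserved. Per-offspring *migration*
probabilities are deliberately **not** rescaled: multiplying them by
1/scale would preserve Nm but would make a few percent of sampled
haplotypes recent migrants, a qualitatively different regime from the
nominal scenarios where individual migrants are vanishingly rare. Scaled
deme sizes are floored so every deme retains at least `samples_per_deme`
haplotypes to sample.

### What the simulations do and do not show

The simulator reproduces neutral drift, divergence, admixture and
migration, which is what the scenario conclusions rest on. It does not
model selection, sequencing error, missing data, reference bias or
diploid consensus artefacts, so a passing scenario suite demonstrates the
statistical behaviour of the method under clean neutral demography, not
its robustness to real-data noise. Note also that at these deme sizes the
coalescent variance is substantial and scale-free: in a minority of
random realisations a deme's internal most-recent-common-ancestor
predates the population splits, producing outlier haplotypes or deep
within-deme families that legitimately attract their own cluster. Exact
recovery (K = 3 with AMI = 1.0) therefore holds in most but not all
seeds, which mirrors how single published runs of such scenarios can look
cleaner than the long-run average.

## The sketch comparison workflow

The comparison approach replaces frequency vectors with presence/absence:
each genome is reduced to a bottom-s MinHash sketch of its filtered
canonical k-mer set (seeded 64-bit hash, truncated to 53 bits so values
are exact in doubles; only internal consistency is claimed, not
bit-compatibility with other tools). The Jaccard index of two k-mer sets
is estimated from the s smallest values of the merged sketches, converted
to a Mash distance d = -(1/k) ln(2j/(1+j)) (saturating at 1 when j = 0),
and the pairwise distance matrix feeds a neighbor-joining tree. Negative
NJ branch lengths are clamped to zero. Recovery of the labeled populations
is judged by monophyly, implemented as an exact unrooted-bipartition test
(a group is monophyletic iff some edge splits the leaves into the group
and its complement, making the test symmetric in a group and its
complement). `monophyly_sweep()` grids this over k-mer lengths and sketch
sizes, the axes on which the approach's accuracy is known to turn.

## Numerical choices and degenerate inputs

* Constant features standardize to zero rather than being dropped; their
  count is logged.
* PCA component signs are fixed (largest-magnitude loading positive) for
  platform-stable output; with zero total variance the scores are all
  zero and a warning is raised.
* K-means ties in assignment break toward the lowest center index; labels
  are canonicalised by first appearance so output is invariant to sample
  order; when the data have fewer distinct points than K the assignment
  is computed directly instead of iterating Lloyd.
* AMI of two trivial single-cluster partitions is defined as 1 (they
  agree); if only the normaliser degenerates the score is 0.
* Windows containing non-ACGT symbols are skipped, not errors; lowercase
  (soft-masked) input is uppercased; k is capped at 31 so 2-bit packing
  stays an available implementation strategy.
* An empty intersection of profiles, an empty sketch and a weak elbow all
  warn rather than fail, since each is a legitimate outcome on real data.

## Problem sizes used by the test-suite

Unit fixtures use three isolated demes of effective size 4 drifting for 80
generations over 8-20 kb genomes, which separates demes by several times
the within-deme diversity in seconds of runtime. The scenario suite runs
the library at scale 0.01 over 10 seeds each, and simulator calibration
checks mean pairwise diversity against E[pi] = theta = 0.005 in a single
deme of 60 haplotypes run for five coalescent times (tolerance 30%, the
Monte-Carlo spread of 10 seeds).

## Known limitations

* Exact, in-memory counting only: genome-scale (Gb) inputs need an
  external counter; this package targets desk-scale analyses and
  simulation studies.
* No fractional/admixture membership estimation -- K-means gives hard
  assignments, so admixed samples land in whichever cluster is nearest.
* The elbow heuristic, however formalised, can be genuinely undecidable;
  consumers should inspect `weak_elbow` and the scree plot rather than
  trust K blindly.
* Mash-style significance testing (p-values) and sketch containment
  scores are out of scope.
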