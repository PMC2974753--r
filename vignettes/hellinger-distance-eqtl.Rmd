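---
title: "Prioritizing expression traits by Hellinger distance in eQTL studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing expression traits by Hellinger distance in eQTL studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdeqtl)
```

## The problem

In an eQTL (expression quantitative trait locus) study on a haploid
biparental cross, every expression trait is tested for association against
every genotyped marker. The standard guard against the resulting multiple
testing burden is a permutation test: the genome-wide maximum association
statistic is recomputed under many random reassignments of strain labels,
and an observed association is called significant only if it beats most of
those null maxima. This family-wise control is deliberately stringent, so
moderate but real genetic effects — often the ones sitting just below the
cutoff — are systematically missed.

`hdeqtl` implements a complementary, per-trait view. Instead of asking "is
this association extreme relative to everything tested genome-wide?", it
asks "does this trait's profile of corrected p-values across all loci look
like the profile of a trait controlled by a single locus?" The answer is a
single number per trait, a Hellinger distance, which can be ranked,
thresholded, and fed into hotspot and cis/trans analyses without touching
the genome-wide error control that produced the p-values.

## The association stage

For a haploid panel coded 0/1, the single-marker LOD score is computed
through the correlation identity

$$\mathrm{LOD} = -\frac{n}{2}\,\log_{10}\!\left(1 - r^2\right),$$

where $r$ is the Pearson correlation between genotype codes and expression
over the $n$ pairwise-complete strains. This is algebraically the
likelihood-ratio LOD of the two-group regression model, the standard
statistic for a backcross-coded haploid panel. Scores are undefined (and
propagated as missing, never as zero) when fewer than 3 complete strains
remain or when either variable is constant; perfect separation is capped at
`lod_cap = 300` to keep the matrix finite.

The permutation null (`permutation_null()`) applies one shared permutation
of strain labels per iteration, recomputes every LOD, and records the
genome-wide maximum. A shared permutation preserves both the linkage
structure among markers and the correlation structure among traits, which
is what the distribution of the genome-wide maximum depends on; an
independent per-trait mode is available via `mode = "per-trait"`. Corrected
p-values use the add-one estimator

$$p(t, m) = \frac{1 + \#\{\text{null maxima} \ge \mathrm{LOD}(t, m)\}}{N + 1},$$

which lives in $[1/(N+1), 1]$, never reaches zero, and is a non-increasing
step function of the LOD with at most $N + 1$ distinct values. The default
$N = 1000$ iterations keeps the p-value floor at roughly $10^{-3}$; the
analyses in this package's test suite use $N$ between 200 and 500 to keep
simulation studies fast at their problem sizes (around 200 traits, 100
markers, 50 strains).

## The Hellinger distance statistic

For each trait, the vector of corrected p-values across the $L$ loci is
mapped to significance scores $s = 1 - p$, so the mass of non-significant
associations ($p \approx 1$) collects near zero and an exceptional
association approaches one. The scores are binned into `n_bins = 30`
equal-width bins over their own range (binwidth = (max − min)/30, bins
half-open on the right with the last bin closed), and the resulting
histogram $P$ is compared with the histogram $Q$ of a reference
distribution: the cubes $\{x^3 : x = 1 \dots L\}$, binned the same way over
their own range. The default comparison is the Hellinger distance

$$d_H(P, Q) = \sqrt{\sum_a \left(\sqrt{P_a/|P|} - \sqrt{Q_a/|Q|}\right)^2}
\in [0, \sqrt{2}],$$

computed positionally, bin $a$ against bin $a$. Because only bin
proportions enter, the statistic compares the shapes of the two
distributions and is invariant to the number of values in each
(`formula = "printed"` switches to the plain squared-proportion sum
$\sum_a (P_a/|P| - Q_a/|Q|)^2$ with range $[0, 2]$; it induces a slightly
different but strongly rank-correlated ordering, and never changes
which marker is a trait's best marker).

The cubic reference concentrates about $(1/30)^{1/3} \approx 32\%$ of its
mass in the first bin and tapers off to a single largest value. It is a
model of the score profile of a trait governed by one locus in linked
territory: most loci contribute nothing, a handful of markers linked to the
causal one form a decaying ladder, and one association stands out. Traits
whose profiles match this shape get small distances; traits whose profiles
deviate — in either direction — get large ones.

Two behaviors of this construction are worth understanding before
interpreting a ranking:

* **Degenerate profiles sit at the top.** A trait whose corrected p-values
  are all (nearly) equal — the typical unregulated trait, since LODs below
  the smallest null maximum all map to exactly $p = 1$ — produces a
  histogram with all mass in bin 1. That histogram attains the maximum
  achievable distance to the reference,
  $\sqrt{2 - 2\sqrt{Q_1/|Q|}} \approx 0.93$ at 30 bins, and any spreading
  of mass into later bins can only decrease the distance. The large tail
  of the distance distribution is therefore dominated by traits with no
  distinguishing association, exactly the traits the method is designed to
  deprioritize.
* **The ranking orders traits by profile spread, not by effect count.** A
  trait with several moderately strong loci has a more spread-out score
  profile than a pure-noise trait, so it lands *between* the single-locus
  traits and the unregulated ones. The statistic cleanly separates
  single-locus traits (small distances) from unregulated traits (maximal
  distances); it does not, and cannot, rank moderately polygenic traits
  above unregulated ones, because nothing can exceed the degenerate
  ceiling. Simulation studies on the synthetic cross confirm both halves
  of this picture.

The number of bins is a tuning parameter with a mild effect: Spearman rank
correlations of the per-trait distances across 10–100 bins (step 10) stay
above 0.9 on the default synthetic cross (`bin_sweep()`), so 30 bins is
retained as a reasonable default granularity for profiles of a few hundred
loci.

## Tails, hotspots, and cis/trans calls

`hd_tails()` selects the traits with the smallest and largest distances,
either by a quantile (`tail_fraction = 0.05`, type-7 quantiles, rank-based
with ties broken by trait id) or count-matched (`n = ...`), e.g. matching
the number of genome-wide significant traits so that overlap fractions are
comparable between methods.

Each selected trait is assigned to the marker with its smallest corrected
p-value (`assign_traits()`; ties, which the step-function p-values make
common, go to the lowest marker index and are counted per trait). Marker
assignment counts are compared with a simulated null in which the same
number of traits is scattered uniformly over the markers
(`hotspot_null()`). Two thresholds are available:

* `mode = "pooled"` (default): the 95th percentile of the per-marker
  counts pooled across iterations. Appropriate when many traits are
  assigned; with very few traits (0–2) the pooled 95th percentile
  degenerates to zero and every occupied marker would be flagged.
* `mode = "max"`: the 95th percentile of the per-iteration maximum count —
  the family-wise analogue, the same construction the permutation test
  applies to LODs. This is the appropriate null for the question "is the
  most-loaded marker surprising?", and it is what the package's hotspot
  sensitivity/specificity simulations use.

A marker is a hotspot when its count strictly exceeds the threshold;
adjacent flagged markers are merged into regions for chromosome-level
summaries. Traits with a chromosome annotation are classified cis if their
assigned marker lies on their own chromosome, trans otherwise.

## The synthetic cross

`simulate_genotypes()` models each chromosome of each haploid strain as a
two-state Markov chain: the first marker is Bernoulli(0.5) and each
adjacent interval recombines with probability `recomb_fraction = 0.1`,
giving the classical $1 - 2r = 0.8$ correlation between adjacent markers
with no crossover interference. `simulate_expression()` plants three trait
classes: single-locus traits $\beta g_m + \varepsilon$, polygenic traits
$\sum_k \beta_k g_{m_k} + \varepsilon$ with causal loci drawn without
replacement, and null traits of pure Gaussian noise.

Default effect sizes are expressed per noise standard deviation. A
single-locus trait uses $\beta/\sigma = 2$, which with $\mathrm{Var}(g) =
1/4$ gives a locus explaining half the trait variance — a strong but
realistic major eQTL, comfortably detectable at 50 strains. Polygenic
traits use 5 loci at $\beta/\sigma = 1$ each, so their total genetic
variance (1.25) matches the single-locus class while no individual locus
is exceptional — the "regulated by several comparable loci" archetype. The
default cross (5 chromosomes × 20 markers, 50 strains, 50 single-locus,
50 polygenic, 100 null traits) is sized so that the full pipeline with 500
permutations runs in seconds, which is what allows the replicated
simulation studies in the test suite.

The generator emulates segregation, linkage, planted architectures, and
optional missing genotype calls. It does not emulate microarray
measurement noise structure, expression heteroskedasticity, epistasis,
population structure, or diploid genetics — so a passing simulation study
says the method behaves as designed under clean Mendelian segregation with
Gaussian noise, not that it is robust to the full messiness of real
expression data.

## Numerical conventions

* Histogram bins: half-open $[\mathrm{lo}, \mathrm{hi})$, last bin closed;
  all-equal inputs put the whole mass in bin 1.
* Corrected p-values: add-one estimator; missing LODs propagate as missing
  p-values and never enter histograms or argmin bookkeeping.
* Tie-breaks: argmin-p ties go to the lowest marker index, consistently
  between `hd_statistics()` and `assign_traits()`; hd ties in tail
  selection break by trait id.
* Quantiles: type 7 for hd tails, type 1 (inverse ECDF) for hotspot count
  thresholds so thresholds stay on the integer count scale.
* Determinism: every stochastic stage takes an explicit seed and is
  bit-reproducible for a fixed seed; the command-line driver writes the
  full effective configuration next to its outputs.

## Limitations

The per-trait distance inherits the resolution of the corrected p-values:
with $N$ permutations there are at most $N + 1$ distinct p-values, and all
LODs below the smallest null maximum collapse to $p = 1$, which is what
pins unregulated traits to the degenerate ceiling. Rankings among traits
with very similar profiles are correspondingly coarse. The statistic is
also blind to marker order — it sees the multiset of p-values, not their
genomic arrangement — so linkage enters only through how it shapes the
profile, and two traits with identical profiles on different chromosomes
are indistinguishable.
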