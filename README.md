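# hdeqtl

Prioritization of expression traits in eQTL studies by the Hellinger
distance between each trait's genome-wide corrected p-value profile and a
reference distribution modelling a single exceptional association.

## The problem

eQTL mapping on a haploid biparental cross (yeast segregants, *Plasmodium*
progeny, and similar panels) tests every expression trait against every
marker. Permutation-based family-wise correction keeps the false-positive
rate in check but buries moderate, real genetic effects just under the
genome-wide cutoff. `hdeqtl` ranks traits by a complementary, per-trait
criterion: how closely the distribution of a trait's corrected p-values
across all loci matches the shape expected of a trait controlled by a
single locus. Traits near the small end of that ranking are candidates for
single-locus control — including overlooked associations that narrowly
missed genome-wide significance — while the large end collects traits with
no distinguishing association.

## The method

For trait $t$ and marker $m$ over $n$ pairwise-complete strains,

$$\mathrm{LOD}(t,m) = -\tfrac{n}{2}\log_{10}(1 - r^2),$$

with $r$ the Pearson correlation between the 0/1 genotype codes and
expression. A permutation null of genome-wide maximum LODs ($N$ shared
strain-label permutations) yields corrected p-values
$p = (1 + \#\{\text{null maxima} \ge \mathrm{LOD}\})/(N+1)$.

Each trait's p-values are mapped to scores $1 - p$, binned into 30
equal-width bins over their range, and compared with the equally binned
cubic reference $\{x^3 : x = 1..L\}$ by

$$d_H(P,Q) = \sqrt{\sum_a \big(\sqrt{P_a/|P|} - \sqrt{Q_a/|Q|}\big)^2}.$$

Small $d_H$ flags a profile dominated by one exceptional association.
Traits in the tails of the $d_H$ distribution are assigned to their
argmin-$p$ marker; markers carrying more traits than a uniform-assignment
null's 95th-percentile count are called regulatory hotspots, and traits
are classified cis or trans by whether their assigned marker shares their
chromosome.

## Worked example

```r
library(hdeqtl)

sim <- simulate_cross(sim_config(), seed = 42)   # default synthetic cross
run <- run_pipeline(sim$geno, sim$expr, n_perm = 500, seed = 42)
print(run)
#> Hellinger-distance eQTL run
#>   traits: 200, markers: 100, permutations: 500
#>   eQTL traits at alpha = 0.05: 60
#>   hd range: [0.8062, 0.932]; 10 traits per tail
#>   hotspot markers flagged: 2 (threshold 1)
#>   count-matched tail overlap with eQTL traits: small 44 (73.3%), large 0 (0%)

head(run$hd[order(run$hd$hd), ], 5)
#>         trait        hd best_marker      best_p n_ties
#> 56  trait0056 0.8061758  chr03_m004 0.011976048      1
#> 100 trait0100 0.8266723  chr03_m009 0.053892216      1
#> 82  trait0082 0.8359118  chr05_m006 0.001996008      1
#> 98  trait0098 0.8446336  chr01_m016 0.011976048      1
#> 34  trait0034 0.8520954  chr01_m011 0.001996008      2
```

Of the 200 simulated traits, 60 reach genome-wide significance at
$\alpha = 0.05$. Matching that count from each end of the Hellinger
distance ranking, 73% of the smallest-distance traits also carry eQTLs
while none of the largest-distance traits do — the ranking concentrates
genuinely regulated traits at the small end. Note trait 100 in the head of
the ranking: its best corrected p-value (0.054) misses genome-wide
significance, yet its profile shape marks it as a single-locus candidate —
exactly the kind of near-cutoff association the method is meant to
surface. `write_run(run, "out/")` writes `assoc.tsv`, `hd.tsv`,
`hotspots.tsv`, `cis_trans.tsv`, `overlap.tsv` and a metadata sidecar.

The same pipeline is scriptable end to end:

```sh
Rscript inst/cli/hdeqtl.R simulate --out data --seed 42
Rscript inst/cli/hdeqtl.R all --geno data/genotypes.tsv \
    --expr data/expression.tsv --out results --n-perm 500 --seed 42
```

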