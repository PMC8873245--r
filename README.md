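# otomove

Reconstruction of within-river movement histories and life-history
strategies of facultative amphidromous fish from LA-ICP-MS otolith
elemental transects.

## The problem

Otoliths (fish ear-bones) accrete calcium carbonate throughout life and
record the trace-element chemistry of the water the fish occupied. A laser
ablation transect through the otolith core therefore yields a chronological
multivariate series of element:Ca molar ratios — a lifetime record of
habitat occupancy. For facultative amphidromous species (e.g. *Galaxias*
riverine populations), the question is whether an individual recruited in
fresh water, in an estuary, or moved between the two (amphidromy), and how
far along the river it travelled.

`otomove` implements the full inference chain:

1. **Ingestion** — wide/long CSV transect tables, element registry,
   detection-limit filter (an element is dropped when > 25% of its pooled
   readings are below the detection limit).
2. **Core detection** — the otolith primordium is located at the maximum
   of the moving-median-smoothed Mn series (the core region is
   Mn-enriched); a core is called only when peak/median prominence ≥ 3.
   Transects are re-oriented core → edge.
3. **Chronological segmentation** — recursive binary partitioning of the
   multivariate series: each split minimises the total within-segment sum
   of squared deviations (on per-element z-scores), stopping on a relative
   cost-reduction threshold. Partition fingerprints are per-element means
   on the original scale.
4. **Element selection** — ensemble-classifier permutation importance
   (percent mean decrease in accuracy) of each element for discriminating
   sampling sites within each river system; an element is dropped only if
   it scores < 5% in *every* river system.
5. **Location models** — per-river random-forest classifiers trained on
   last-partition fingerprints and coreless-fish edge signatures (2–7 µm
   sub-surface window), with out-of-bag (OOB) accuracy distributions over
   100 seeded fits, and a strict independence rule: a fish whose
   partitions are being predicted never contributes its last partition to
   the training set of the model that evaluates it.
6. **Movement reconstruction** — partition-level majority-vote location
   predictions become movement events (upstream / downstream / lateral via
   river-km), displacement distances, estuarine-signature flags (binary
   pooled-estuary classifier), and life-history labels
   (freshwater resident / estuarine resident / amphidromous).
7. **Habitat statistics** — one-way PERMANOVA (Euclidean pseudo-F,
   permutation p with automatic exact enumeration at small n), pairwise
   post hoc comparisons (t = √pseudo-F), rank-based per-element tests, and
   a per-location seasonal-stability check.
8. **Synthetic cohorts** — a generator of transects with known site
   fingerprints (Sr-enriched estuary, Rb-enriched fresh water), AR(1)
   noise, Mn core peaks, movement scenarios and ground-truth labels, so
   every stage is verifiable without laboratory data.

The classifier is a self-contained Rcpp implementation of the classical
random forest (CART/Gini trees on bootstrap resamples, OOB voting,
permutation importance); the PERMANOVA permutation loop is also in C++.

## Statistic at the core

For groups \(g = 1..a\) with sizes \(n_g\) and a Euclidean distance matrix
\(d_{ij}\) over \(N\) edge fingerprints, the pseudo-F is

```
SS_total  = (1/N) * sum_{i<j} d_ij^2
SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2
F = [(SS_total - SS_within)/(a-1)] / [SS_within/(N-a)]
```

with `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` under free label
permutation (exact enumeration when the number of distinct relabellings
does not exceed `n_permutations`).

## Worked example

```r
library(otomove)

template <- default_river_template(3, separation_sd = 5, seed = 1)
config   <- cohort_config(template, default_scenarios(template, 30L),
                          n_fish_per_scenario = 20L, seed = 18L)
cohort   <- simulate_cohort(config)
report   <- run_pipeline(cohort$transects, cohort$sites,
                         params = pipeline_params(n_permutations = 999L),
                         seed = 1)
print(report)
```

Output from this exact run:

```
<pipeline_report> seed 1
  fish: 67 cored + 13 coreless
  elements retained: Rb, Sr
  synthetic: OOB accuracy 1 +/- 0
  recruitment:
         life_history  n proportion percent
1 freshwater_resident 34  0.5074627      51
2  estuarine_resident 17  0.2537313      25
3        amphidromous 16  0.2388060      24
4        undetermined  0  0.0000000       0
PERMANOVA (Euclidean): pseudo-F = 13397.6, p = 0.001 (999 permutations)
```

Reading it: 67 of 80 simulated fish had a detectable Mn core peak and were
reconstructed; the importance filter kept the two gradient elements (Sr,
Rb); site classification was error-free at this centroid separation
(OOB accuracy 1); the recruitment table is the per-fish life-history
summary over the cohort (the generating mixture, restricted to cored fish,
is recovered exactly here); the PERMANOVA confirms the habitat separation
of edge fingerprints at the permutation-resolution p-value.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tracer.R", package="otomove"))')" \
    simulate --out /tmp/sim --seed 3 --fish 6
Rscript "$(Rscript -e 'cat(system.file("cli/tracer.R", package="otomove"))')" \
    run --transects /tmp/sim/transects.csv --sites /tmp/sim/sites.csv --seed 3
```

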