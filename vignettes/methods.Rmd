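---
title: "Methods: otolith transect segmentation, provenance assignment and life-history classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: otolith transect segmentation, provenance assignment and life-history classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomove)
```

## The model

An otolith ablation transect is a chronologically ordered multivariate
series: positions in µm along the laser path, one concentration (molar
ratio to ⁴³Ca) per monitored element per position. The package's model of
that series is piecewise-stationary residence: a fish occupies a sequence
of habitats, each with a characteristic multivariate elemental
fingerprint, and the transect is (habitat mean) + (autocorrelated
measurement/physiology noise), with change-points at the habitat
transitions. Three consequences structure the pipeline:

* the **core** must be located first (the chronology starts at the
  primordium), which is possible because primordial material is
  Mn-enriched;
* **segmentation** is a change-point problem on an ordered series, not a
  clustering problem — partitions must be contiguous in time;
* **provenance** of a partition is decided by comparing its fingerprint
  with the fingerprints of material of known origin: otolith edges (2–7 µm
  below the surface), which record the habitat occupied just before
  capture.

Key assumptions, inherited from the field's practice: element uptake
reflects ambient water chemistry well enough that site fingerprints are
stable within a sampling campaign (checked by the seasonal PERMANOVA);
edge material of a captured fish reflects its capture site; and the
estuary–freshwater contrast is dominated by Sr (higher in estuaries) and
Rb (higher in fresh water).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dl_threshold` | 0.25 | fraction | an element is excluded when **more than** 25% of pooled readings are below detection limits; strictly-greater, pooled over the run |
| `edge_window` | [2, 7] | µm from surface | sub-surface averaging window, both ends inclusive; material < 2 µm is unreliable (surface contamination/irregularity) and never used |
| `smooth_window` | 5 | points | moving-median width for Mn smoothing; robust to single-shot ablation spikes |
| `min_prominence` | 3 | ratio | smoothed Mn peak ÷ series median required to call a core |
| `edge_exclusion_fraction` | 0.1 | fraction | transect ends excluded from the peak search (ablation on/off artefacts) |
| `limb_rule` | longer | — | limb kept after orientation; ties go to the declared surface end, else the later-acquired limb |
| `min_seg_len` | 5 | points | minimum partition length |
| `max_partitions` | 6 | — | cap on partitions per transect |
| `penalty` | 0.05 | fraction | a split must reduce total within-segment cost by at least this fraction |
| `importance_threshold` | 5 | % MDA | element kept unless below this in **every** river system |
| `ntree` | 500 | trees | ensemble size per fit |
| `oob_runs` | 100 | fits | OOB accuracy distribution size |
| `estuary_threshold` | 0.5 | vote proportion | partition flagged estuarine at or above this |
| `n_permutations` | 9999 | — | PERMANOVA resolution 10⁻⁴ |
| `prediction_batches` | 2 | — | holdout folds for partition prediction (below) |

## Numerical and algorithmic choices

**Segmentation cost.** Split placement minimises total within-segment sum
of squared Euclidean deviations computed on per-element z-scores (each
element centred/scaled by its own mean and sd over the fish's series).
Without this, Sr (10⁻³) would dominate Li (10⁻⁶) purely by scale.
Fingerprints are averaged on the *original* scale. Splitting is greedy
top-down ("recursive partitions"): at each step the globally best single
split among current segments is taken; the exhaustive optimal tiling
exists only as a brute-force oracle in the test suite, where greedy and
exhaustive agree on well-separated fixtures. Equal-cost splits go to the
smallest index. Indices are half-open 0-based `[start, end)`. A constant
series (zero total cost) yields one partition; a series shorter than
`2 * min_seg_len` yields one partition rather than an error.

**Stopping rule.** The source method states no stopping criterion; we
stop when the best split's cost reduction, relative to the current total
cost, falls below `penalty`, or at `max_partitions`, or when no split
respects `min_seg_len`. Decreasing `penalty` can only refine (never
coarsen) a segmentation — a tested monotonicity property.

**Core detection ties.** A moving median flattens the top of a symmetric
peak, so the smoothed maximum can be a short plateau; the first index
wins. Detection is therefore guaranteed only to within the plateau
(±2 points in the acceptance criterion), which is immaterial at 1 µm
spacing. Prominence is a ratio, so the call is invariant to rescaling Mn;
the search skips `edge_exclusion_fraction` of points at each end, so a
core cannot be called at the transect boundary.

**The classifier.** The environment provides no random-forest
implementation, so the package carries its own (Rcpp): fully grown CART
trees with Gini splits, `mtry = floor(sqrt(p))` candidate features per
node, bootstrap resampling, OOB voting, and unscaled permutation
importance (mean decrease in OOB accuracy, in percent). Determinism
follows R's RNG (`set.seed` before each fit; all pipeline fits are seeded
from the global seed via a per-stage hash, so adding a stage does not
shift another stage's stream). The deployed model of the repeated-OOB
evaluation is the fit whose OOB accuracy is closest to the median of the
distribution. Vote ties at prediction go to the alphabetically earlier
site and are flagged.

**Independence rule and batching.** A fish whose partitions are evaluated
must not contribute its last partition to the training set of the model
evaluating it. Holding out *all* evaluated fish at once would leave
training classes populated only by coreless-fish edges, which can be
empty at a site by chance. The pipeline therefore predicts in
`prediction_batches` folds: fish are split deterministically, and each
batch is predicted by a model trained on the other batches' last
partitions plus all coreless edges. The audit (empty intersection of
trained-on and evaluated fish) is asserted programmatically on every
batch. OOB summary statistics come from a separate model trained on the
full pool, matching how repeated-OOB evaluation is reported.

**PERMANOVA.** Euclidean pseudo-F from Anderson's distance partitioning;
free permutation of labels (equivalent in distribution to residual
permutation in a one-way design). When the number of distinct label
arrangements is ≤ `n_permutations` the test enumerates them all and the
p-value is exact (`#{F ≥ F_obs}/N`, identity included); otherwise
`p = (1 + #{F_perm ≥ F_obs})/(1 + n_permutations)`. Pairwise tables
report `t = √F` with unadjusted permutation p (flag at α = 0.05, matching
the conventional post hoc presentation) alongside Holm-adjusted values.
Per-element tests are rank-based (Kruskal–Wallis with pairwise Wilcoxon
follow-ups) because the corresponding supplementary method is not
specified; directional summaries name the group with the highest median.

**Life-history rules.** A partition is estuarine when the pooled-estuary
binary classifier's estuarine vote proportion is ≥ `estuary_threshold`.
Amphidromous ⇔ at least one estuarine and one non-estuarine partition;
estuarine resident ⇔ all partitions estuarine and capture in an estuary;
freshwater resident ⇔ no estuarine partition; the residual contradictory
case (uniformly estuarine signal, freshwater capture) is labelled
`undetermined` rather than silently forced — the source classification
has no such category, but a robust artifact needs one. Movement direction
uses along-river km (upstream/downstream/lateral); displacement is the
km range over visited sites. The first partition is reported as "earliest
recorded", not asserted to be strictly natal.

## The synthetic world

`default_river_template()` builds per-site fingerprints on an
estuary-to-upstream gradient: Sr decreases upstream, Rb increases, other
elements get only a small seeded jitter. The gradient is deliberately
**non-linear**: the estuary→freshwater step in Sr and Rb is
`estuary_sr_boost` (default 5) times the step among freshwater sites.
This mirrors the empirical structure of such systems — post hoc
habitat comparisons show estuary-vs-freshwater statistics roughly an
order of magnitude stronger than differences among freshwater habitats —
and it is what makes a pooled estuary-vs-freshwater detector meaningful:
with a linear gradient, a middle-river fingerprint would sit exactly
between the two training classes and its estuarine vote would be a coin
flip. Adjacent sites are separated by at least `separation_sd` pooled
standard deviations; `separation_sd = 0` collapses all sites.

`simulate_fish()` concatenates residence segments (site mean + AR(1)
noise, φ = 0.3 by default, since adjacent ablation points are
correlated), adds a Gaussian Mn core peak (height 8× the Mn baseline,
width 2.5 points) unless the fish is drawn coreless, and prepends a short
opposite-limb stub (15% of the chronological length) before the core —
the real ablation crosses the whole otolith, so the core peak must sit in
the transect interior for interior-restricted peak search to find it.
Concentrations are clipped at a small positive floor (clips counted).
Base element levels are realistic molar-ratio magnitudes (Sr/Ca ~ 1.5
mmol/mol, Rb/Ca ~ 1 µmol/mol, etc.) with per-element sd 8% of the mean.

What the generator does **not** emulate: temperature/growth-rate effects
on element uptake, ontogenetic drift, detection-limit censoring of real
instruments (below-DL flags are optional Bernoulli draws), irregular
ablation spacing, and inter-individual physiological variation beyond
AR(1) noise. A green end-to-end test therefore establishes that the
inference chain is correct *under the piecewise-stationary model it
assumes*, not that field data meet that model.

## What the tests establish

The acceptance suite asserts: exact agreement of greedy segmentation with
an exhaustive oracle on 50 well-separated fixtures; fingerprint
conservation to 10⁻¹⁰; ≥ 99% core detection within ±2 points over 1000
fixtures (flat series always "absent"); the strict detection-limit
boundary (25% retained / 26% excluded); location-model OOB ≥ 0.95 at 10
pooled-sd separation and chance-level OOB (±0.1 of 1/3) on null data with
the independence audit passing; ≥ 90% end-to-end life-history recovery on
a mixed 80-fish cohort at 5 sd separation with correct estuarine
flagging; PERMANOVA type-I error in [0.03, 0.07] over 500 null
simulations and exact equality of the small-n permutation p with
enumeration; byte-identical reruns of every stochastic stage under a
fixed seed.

## Known limitations

* The chronology is ordinal: no age model or daily-increment calibration,
  so "when" a movement happened is expressed in partition rank, not time.
* Each river system is modelled separately; there is no cross-river
  transfer, and vote proportions are not calibrated probabilities.
* The greedy splitter can in principle miss a globally optimal tiling
  when discontinuities are weak relative to noise; the penalty/stopping
  configuration is exposed and logged for that reason.
* With very small cohorts the batched independence rule can still leave
  a site class thin; the training-set builder warns on classes with fewer
  than two rows.
* Registry default for Ba is mass 138; inputs declaring another monitored
  mass are stored as declared.
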