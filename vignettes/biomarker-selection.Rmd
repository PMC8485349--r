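---
title: "Biomarker selection from label-free proteomics: methods and design choices"
author: "chemoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker selection from label-free proteomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoselect)
```

## The problem

Label-free, data-independent-acquisition proteomics (SWATH-type) yields a
complete samples × proteins abundance matrix. A typical biomarker study
contrasts two biological conditions — here, meat-maturation timepoints of
bovine *Longissimus dorsi* muscle — and asks which proteins change. The
study design this package emulates measures 8 animals (4 heifers, 4 bulls)
at three timepoints (t0, t12, t26 days of aging), each biological sample in
3 technical replicates, with one t12 biological sample discarded: 69 rows
(24 / 21 / 24 per timepoint) described by 137 protein signals. Four
two-class comparisons are analyzed: t0 vs t12 (early aging), t12 vs t26
(late), t0 vs t26 (long), and t0 vs t12+t26 (general).

`chemoselect` implements the complete statistical workflow — univariate
screening, PCA, self-organizing maps, and PLS-DA with VIP-driven backward
elimination under repeated cross-validation — together with a synthetic
generator that plants known effects, so that the whole pipeline is testable
against ground truth.

## The synthetic-data generator

Abundances are log-normal: for replicate measurement *k* of animal *i* at
timepoint *t*,

```
x[i,t,k,p] = exp( base[p] + animal[i,p] + beta[p,t] + gender[p]·1(female)
                  + bio[i,t,p] + tech[i,t,k,p] )
```

* `base[p] ~ U(9, 14)` on the log scale (arbitrary intensity units spanning
  roughly 8·10³–10⁶, as typical of label-free signal).
* A coefficient of variation *c* corresponds to a log-sd of
  `sqrt(log(1 + c²))`. The **biological CV** (default 0.30) is split evenly
  between a persistent animal effect and per-biological-sample variation;
  the **technical CV** (default 0.10) acts independently on every
  replicate. The study reports no variance components, so these defaults
  are free parameters chosen as typical SWATH intensity CVs, not estimates
  from any dataset; the invariant that matters — technical spread smaller
  than biological spread, which is what makes technical replicates
  co-locate on the SOM — is enforced (`technical_cv < biological_cv`).
* Planted proteins follow step trajectories on the log scale: "early"
  proteins shift by `log(planted_fc)` from the second timepoint onward,
  "late" proteins only at the last timepoint; onsets alternate so every
  pairwise contrast has truly discriminant proteins. Fold changes are
  planted on biological means; technical replicates resample only technical
  noise. The default plants 20 proteins at FC 2.
* The discarded sample defaults to the first female animal at t12,
  reproducing the study's 69-row structure.
* Phenotypes are generated per biological sample as
  `r·z(protein) + sqrt(1−r²)·noise`, where `z` is the standardized
  biological-level log abundance, so the achieved Pearson correlation
  approaches the target `r` at large n.
* Every random draw flows from an explicit `seed` field; equal specs and
  seeds give bit-identical datasets.

**What the generator does not emulate:** missing values (the emulated
matrix is complete), peptide-level quantification and rollup,
identification FDR, heteroscedastic mass-spectrometric error, and
correlated protein modules (proteins are conditionally independent given
the design). Passing tests therefore demonstrate correctness of the
algorithms under a clean log-normal model, not robustness to every
pathology of real data.

## Univariate screening

Per protein, a two-sided two-sample t-test (Student's pooled-variance by
default, Welch optional) on raw abundances, plus the fold change
`FC = mean(class b)/mean(class a)` on raw class means at the
technical-replicate level. A protein is dysregulated when `p < 0.05` AND
(`FC > 1.3` OR `FC < 0.769`); both comparisons are strict, and no
multiple-testing correction is applied — deliberately matching the
original protocol. Both thresholds are independent parameters even though
0.769 ≈ 1/1.3, because the protocol states both.

A calibration caveat documented here because it is easy to miss: under the
crossed design, technical replicates are pseudo-replicates and animal
effects are shared across timepoints, so replicate-level t-tests are
**anti-conservative** (about 14% of null proteins reach p < 0.05 at
nominal 5% under the default generator). The package's calibration checks
therefore verify the nominal 5% rate on an independent-groups design
(each animal contributing one biological sample); users analyzing crossed
designs should read the univariate panel as a screening heuristic, which
is how the workflow treats it.

The shear-force module fits a two-way fixed-effects ANOVA (animal, days,
interaction) on replicate-level Warner–Bratzler force values and reports
per-animal DWBS = mean(day 26) − mean(day 12) with its pooled standard
deviation. Post-hoc comparisons use Tukey HSD; the "Tukey b" procedure is
not exposed by standard R and HSD is the documented substitution.

## PCA

SVD on the (auto)scaled matrix; components ordered by decreasing variance;
the sign of each loading column is fixed so its largest-magnitude entry is
positive, making results deterministic. Explained variance is reported
against the total centered sum of squares, so it sums to 100% at full
rank. Autoscaling uses the sample (n−1) standard deviation — the
mainstream chemometrics convention; the original protocol does not state
the denominator.

## Kohonen self-organizing maps

Batch algorithm on a hexagonal grid with toroidal boundary; grid
dimensions must be even so the lattice closes on the torus. Per epoch:

1. assign every sample to its winning neuron (minimum Euclidean distance;
   ties to the lowest neuron index);
2. compute each neuron's target as the neighborhood-kernel-weighted mean
   of all samples, with Gaussian kernel `h = exp(−d²/2σ²)` in
   hex-toroidal grid distance;
3. blend: `w_new = (1−α)·w_old + α·target`.

The learning rate α decreases linearly from 0.5 to 0.01 and σ decreases
linearly from half the larger grid dimension to 0 (winner-only in the last
epoch). The classical batch SOM has no learning rate; the protocol
prescribes one, and the convex blend above is this package's resolution —
with α = 1 and σ = 0 one epoch reduces exactly to a k-means
assignment+update step, which the tests exploit as an oracle. Neurons
receiving no kernel mass keep their weights for that epoch. Hexagonal
toroidal distance uses cube coordinates with the minimal-image rule over
the nine wrapped copies; it equals breadth-first-search graph distance on
the wrapped hexagonal adjacency, verified exhaustively in the tests.

Defaults mirror the protocol: 10×10 neurons / 300 epochs for the general
(three-timepoint) comparison, 8×8 / 200 for pairwise ones. The exact
kernel and radius schedule of the original MATLAB toolbox are unpublished,
so neuron-level reproduction of the original maps is not attempted; the
reproducible claims are structural (class separation, technical replicates
on the same or adjacent neurons). Interpretation uses PCA on the
neurons × variables weight matrix (centered but not re-scaled — weights
already live in autoscaled data space), with neurons annotated class-a /
class-b / mixed / empty from their assigned samples.

## PLS-DA and VIP

PLS1 via NIPALS against the class indicator coded −1/+1 and centered;
class b is conventionally the later timepoint, so positive regression
coefficients read as up-regulation with aging. Scaling parameters are
stored in the model and re-applied to new samples at prediction; a
decision value of exactly 0 is assigned to class a and flagged. VIP uses
the standard Wold formulation,

```
VIP_j = sqrt( p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a ),
```

with `SSY_a` the class-membership variance explained by latent variable
*a*; the mean of squared VIPs is identically 1. At full rank PLS1
predictions coincide with least squares on the same coding — one of the
oracle equivalences in the test suite, alongside an exact cross-check of
scores and VIPs against `mixOmics`.

## Cross-validation and backward elimination

Validation is repeated leave-more-out: each repeat partitions the samples
into 5 random disjoint cancellation groups of ~20% (remainder samples go
one per group, largest groups first); each group is held out once.
Autoscaling and indicator centering are recomputed on each training fold
only, so no information leaks from held-out samples — the original
toolbox's behavior is unrecorded, and the leak-free variant is the
defensible default. Metrics (accuracy %, non-error rate %, per-class
sensitivity/specificity/precision) are computed per repeat from the pooled
out-of-fold predictions — each sample predicted exactly once per repeat —
then averaged over repeats; with the protocol's fold counts this equals
fold-averaging for accuracy up to fold-size weights while keeping
per-class metrics well-defined. The default is 1000 repeats; tests and
examples run at 100 with correspondingly wider Monte-Carlo tolerance.
Technical replicates are treated as independent samples, which is what the
protocol's sample counts imply; note this makes internal CV optimistic
(sibling replicates of a held-out sample remain in training). A
group-aware split at the biological-sample level is the recommended
refinement for real studies and is deliberately not the default, to keep
the emulated protocol intact.

Backward elimination: fit PLS-DA on the current variable set, record
repeated-CV metrics, compute VIP on the full-data fit, drop the single
lowest-VIP variable (ties to the first index), continue to one variable.
The selected panel is the step with the highest mean CV accuracy; ties go
to the fewest variables. Design choices fixed here where the protocol is
silent:

* **LV count** is selected once on the full variable set (highest mean CV
  accuracy over 1..max_lv, ties to fewest) and capped by the shrinking
  variable count during elimination; per-step re-selection is available
  (`reselect_lv = TRUE`) at max_lv times the CV cost, and did not change
  recovery behavior in simulation.
* **CV partitions are re-seeded identically at every elimination step**, so
  the logged metrics of the selected step are exactly reproducible by
  refitting the selected set under the same scheme.
* **Elimination order** uses VIP from the full-data fit (not CV-averaged
  VIP), matching the protocol's one-sentence description.

Two behaviors of this algorithm are worth understanding before reading
panels:

* With one informative variable among noise, two latent variables often
  genuinely beat one in internal CV — the second LV strips the noise
  picked up by the first (whose weights are proportional to the X–y
  covariance). A single LV wins only when accuracy saturates for every LV
  count and the parsimony tie rule applies.
* When planted effects are strong, CV accuracy saturates at 100% over many
  elimination steps and the fewest-variables tie rule shrinks the panel to
  a minimal subset — possibly excluding a truly discriminant protein whose
  information is redundant. With moderate effect sizes (e.g. FC ≈ 1.4 at
  biological CV 0.3) accuracy does not saturate and the selected
  multivariate panel is typically **larger** than the univariate panel,
  reproducing the qualitative finding that multivariate selection roughly
  doubles the univariate biomarker count.

## Pipeline and problem sizes

`run_comparison()` chains subset → autoscale → univariate screen → PCA →
SOM (+ weight PCA) → backward elimination → metrics, with per-stage seeds
derived deterministically from one master seed so stages are independently
re-runnable; `overlap_summary()` computes the cross-design Venn counts.
The package's own verification runs use reduced problem sizes chosen to
keep Monte-Carlo error small while remaining quick on one CPU: 1000
simulated null datasets for t-test calibration, 50 fresh permutations × 20
CV repeats for the permutation null (a single fixed permutation is *not* a
valid null — its conditional CV accuracy concentrates away from 50%), 20
simulated studies at 100 CV repeats for planted-biomarker recovery, and a
10×10 / 300-epoch map for replicate topology.

## Known limitations

* The univariate screen inherits the protocol's replicate-level testing
  and lack of multiplicity correction; both are anti-conservative.
* Internal CV with technical replicates as independent samples overstates
  generalization to new animals.
* The SOM's neuron-level layout is seed- and kernel-dependent; only
  structural properties are reproducible.
* PLS-DA here is strictly two-class (PLS1); multiclass variants and
  orthogonal-PLS are out of scope, as are GO/STRING/KEGG enrichment steps
  that depend on external services.
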