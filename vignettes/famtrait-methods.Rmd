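---
title: "Methods: predicting a binary stress-resistance trait from gene-family sizes"
author: "famtrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting a binary stress-resistance trait from gene-family sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Across a species phylogeny, gene families expand and contract; the number
of copies a species carries of, say, a reductase family may shape how well
it tolerates oxidative stress. `famtrait` implements a complete analysis
path for asking, genome-wide, *which* gene families' sizes predict a binary
stress-resistance trait:

1. reduce plate-reader growth curves to a per-species *relative growth*
   phenotype;
2. binarize the phenotype with a dual-concentration tail rule;
3. train a random-forest classifier on orthogroup copy numbers, selecting
   the most informative families by Gini importance under a replicated
   holdout/cross-validation protocol;
4. attribute each species' prediction to individual families with exact
   path-dependent TreeSHAP;
5. test count/phenotype associations with phylogenetic generalized least
   squares (PGLS); and
6. ask whether the selected families' member genes are enriched for
   functional terms against a custom background.

A synthetic-data generator with fully known ground truth exercises every
stage, so the pipeline's operating characteristics (causal-family recovery,
null calibration) are measurable rather than assumed.

# Growth phenotypes

A well's growth curve is summarized by its *empirical area under the curve*
(EAUC): the trapezoidal integral of optical density over time, a model-free
growth measure in OD·h. We integrate on the actual timestamps with no
resampling; an hourly grid is simply the common special case. `eauc()`
defaults to no baseline correction — the ratio statistic below is then
exactly the ratio of raw areas — but offers `subtract_initial` (with
clipping at zero) because plate blanks vary between instruments.

*Relative growth* is the EAUC of a treated well divided by the EAUC of the
untreated (dose 0) control well of the same species and replicate; treated
and control are paired by replicate, unmatched or zero-area-control
replicates are dropped with a warning (never silently turned into NaN), and
the remaining per-replicate ratios are averaged, one record per species and
dose. When treated and control were read on different time grids, each
curve is integrated on its own grid.

# The trait classes

The binary trait is defined by two concentrations of the stressor: the
poorest-growing fraction `f` of species at the *low* dose become class 0
(sensitive) and the best-growing fraction `f` at the *high* dose become
class 1 (resistant), with `f = 0.2` by default. Each tail has exactly
`floor(f * N)` members; with 285 species this yields 57 + 57 = 114
instances. Ties at a cutoff are resolved by a stable (value, species) sort,
so permuting the input never changes the classes. A species falling in both
tails means the rule is degenerate for that dataset and is an error, not a
precedence choice. The unclassified middle is retained separately because
count-versus-growth correlations downstream use *all* screened species.

# The random forest

The classifier is a bagged ensemble of axis-aligned CART trees written for
this package (the split search and prediction loops are C++ via Rcpp, the
protocol logic R). Each tree grows on a bootstrap sample of `n` draws with
replacement; at each node a random feature subset is considered (`sqrt`,
`log2`, or a fraction of the columns) and the split maximizing the Gini
impurity decrease

$$\Delta = \mathrm{imp}(parent) - \tfrac{n_L}{n}\,\mathrm{imp}(L)
  - \tfrac{n_R}{n}\,\mathrm{imp}(R), \qquad
  \mathrm{imp} = 1 - \textstyle\sum_k p_k^2,$$

is taken over candidate thresholds at midpoints of consecutive distinct
values. Ties go to the lowest feature index, then the lowest threshold, and
all randomness flows from R's RNG, so training is bit-reproducible from a
seed; there is no parallelism. Growth stops on purity, `max_depth`, or no
positive gain; leaves carry their class counts, and the forest's predicted
probability is the mean over trees of the leaf class-1 fraction.

*Gini importance* of a family is its sample-weighted impurity decrease
`(n_node/n_root) * delta` summed over the nodes that split on it, summed
within each tree, averaged over trees, and normalized to sum to one.

## Feature selection and the evaluation protocol

`evaluate_replicates()` runs, per replicate `r` with seed `base_seed + r`:

* a balanced holdout split — `round(0.1 * N / 2)` species *per class* are
  held out (10% of 114 is not an even number, so the closest balanced
  realization is used) and the rest are partitioned into 10 stratified
  folds by seeded per-class shuffle and round-robin;
* a *selection forest* on the training partition only, whose Gini ranking
  keeps the top 50 families;
* a grid search over forest hyperparameters by mean cross-validated F1
  (ties prefer fewer trees, then shallower depth); a single-cell grid skips
  the search;
* a final 500-tree, depth-10 forest on the full training partition, scored
  on the untouched holdout.

Validation metrics come from pooled out-of-fold predictions computed under
**nested** feature selection: each fold's screen is re-run on the species
outside that fold. Selecting features once and then cross-validating lets
the held-out fold leak into the screen; with 2,000 features and ~100
species that classic leak inflates the null validation AUC from ~0.5 to
~0.75, so nesting is not optional if the validation numbers are to mean
anything. The replicate-level selection (run once on the whole training
partition) still defines the reported feature list, the final model, and
the test metrics, which involve no such leak.

The selection forest defaults to a per-node feature fraction of 0.25 rather
than `sqrt`: with `sqrt(2000) = 44` features per node, most nodes of the
screen never see an informative family at all and importance leaks to
noise; a wider subsample lets informative families compete head-to-head and
stabilizes the ranking. The classifier itself keeps the conventional
`sqrt`.

Per-replicate confusion matrices are row-normalized ("balanced": each row
is the distribution of predictions within a true class) before averaging;
F1 and the confusion matrix use the 0.5 probability threshold, while
ROC/PR curves sweep all thresholds. The mean ROC interpolates each
replicate's step curve onto a fixed false-positive-rate grid
(0, 0.01, ..., 1) and reports the per-point mean and SD of the true
positive rate. Validation AUC is computed on pooled out-of-fold
predictions by default (`pooled = FALSE` gives the per-fold average; the
report records which was used).

# TreeSHAP attribution

For each species, the Shapley value of each family measures its
contribution, in probability units, to that species' predicted probability
of resistance relative to the model's base value: positive values push
toward the resistant class. The value function is the *path-dependent*
conditional expectation — descending a tree, a feature outside the
coalition averages both children weighted by their training coverage —
matching the classical Tree Explainer default. `shap_tree()` implements the
polynomial-time EXTEND/UNWIND recursion per tree; per-tree attributions and
base values are averaged because the forest's output is the mean of its
trees. Two oracles pin it down in the tests: `shap_bruteforce()` evaluates
the exponential Shapley sum over all `2^m` coalitions of the used features
(capped at m = 20), and local accuracy — base value plus attributions
equals the prediction — is asserted to 1e-9 for every explained instance.
`shap_vs_count()` reports, per family, the per-species (copy number, SHAP)
pairs and the minimal separating copy number when the attribution sign is a
threshold function of the count.

Explanations are computed for all instances; when a run has many
replicates, per-replicate SHAP matrices can be averaged, which is a
reporting choice, not a claim about any single model.

# PGLS

Under Brownian motion on the phylogeny, trait covariance between two
species is proportional to their shared root-to-ancestor branch length.
`pgls()` fits `y = b0 + b1 x` by generalized least squares with that
covariance (Pagel's lambda fixed at 1; no branch-length transformation is
estimated), with `beta = (X'V^-1X)^-1 X'V^-1 y`, the slope's standard error
from `sigma2 (X'V^-1X)^-1`, `sigma2 = RSS_V/(n-2)`, and a two-sided t test
with `n - 2` degrees of freedom. The reported phylogeny-adjusted
correlation is the signed square root of the GLS R², where the total sum of
squares comes from the V-weighted intercept-only fit; this definition is
stated here because "R adjusted for phylogeny" admits several readings. On
a star phylogeny with equal branch lengths the whole machinery collapses to
ordinary least squares, which the tests exploit as an exact oracle;
non-ultrametric trees are accepted as-is. Welch t-tests, Pearson
correlations and one-way ANOVA for group comparisons are thin wrappers over
the standard R implementations, verified against closed-form fixtures.

# Enrichment

Over-representation of annotation terms in the selected families' member
genes is tested per term with the upper-tail hypergeometric probability
(one-sided, since only over-representation is reported; a two-sided
Fisher option exists), fold enrichment `(k/n)/(K/N)`, and
Benjamini–Hochberg FDR across all tested terms (the procedure behind the
generic "FDR" is a choice and is declared). Defaults report terms with at
least 5 study genes at FDR < 0.001. The study set must be a subset of the
user-supplied background; annotation input is a flat, pre-propagated
term-to-gene table — ontology graph semantics are deliberately out of
scope. Note that the step-up adjustment is *not* idempotent on already
adjusted values (only tied inputs are fixed points); the tests assert
order-invariance and hand-computed fixtures instead.

# The synthetic-data generator

`make_dataset()` produces a mutually consistent phylogeny, count matrix,
membership table, growth-curve plate, annotation stub and ground truth from
one seed (per-stage streams are derived from fixed offsets of that seed, so
stages regenerate stably). Defaults reproduce the study design the package
targets: 285 species, 2,000 families, 5 causal families, doses 0/1/2 mM in
three replicates, hourly readings for 168 h, and the 20%/20% rule then
yields exactly 57 + 57 = 114 instances.

* **Phylogeny** — a pure-birth (Yule) tree, rescaled to unit depth.
* **Counts** — per family, a geometric root count (P(0) = 0.7) evolved by a
  linear birth–death process (duplication = birth, loss = death, rates 1
  per copy per unit depth). Each branch is sampled *exactly* from the
  process's transient distribution (binomial survival plus a
  negative-binomial tail) rather than event-by-event, which is
  distributionally identical and vectorizes across families; the
  martingale property (critical-case mean preservation) is tested. The
  result is a sparse, zero-inflated, heavy-tailed integer matrix with
  realistic phylogenetic autocorrelation.
* **Trait** — a liability `L = sum(w_c * count_c) + sigma_phylo * BM +
  sigma_iid * eps`, squashed to a resistance score `r = plogis(L -
  median(L))`. Configured weights are in liability units *per count
  standard deviation* (realized per-copy weight `w_c = weight / sd_c`):
  with raw per-copy weights, whichever family has the heaviest-tailed
  counts dominates the trait and the remaining "causal" families are
  causal in name only. Defaults are five equally strong effects
  (3, 3, 3, 3, −3), making the trait almost fully genetic — the regime in
  which recovery of the causal set is a meaningful benchmark.
* **Causal set identifiability** — causal families are chosen by walking
  down the count-SD ranking, requiring bulk variation (IQR ≥ 1, so the
  variance is not carried by two outlier species) and near-orthogonality
  (pairwise |r| < 0.1). Gene-family profiles on a shared tree are
  collinear; without this cap, opposing-weight causal families cancel each
  other's marginal association and *no* method could single out the true
  set — the ground truth itself would be ill-posed. Tiny matrices that
  cannot satisfy the strict criteria fall back to relaxed tiers with a
  warning.
* **Phylogenetic trait noise** — `sigma_phylo = 0.1` versus `sigma_iid =
  0.5`. Because count profiles encode the tree, a strongly heritable
  residual makes even a zero-weight "null" trait genuinely predictable
  from clade-marker families (holdout AUC ≈ 0.9 at equal noise scales);
  the small default keeps the null calibrated and mirrors a trait that
  varies largely independently of taxonomy.
* **Growth curves** — logistic `OD(t) = K/(1 + ((K - N0)/N0) e^{-rho t})`
  with N0 = 0.1, K0 = 1.0 and species growth rates 0.05–0.15 per hour.
  Stress acts on the carrying capacity, `K = K0 * plogis(8 (r - 0.05 -
  0.3 d))` at dose `d` > 0, so the treated/control EAUC ratio increases
  monotonically in true resistance and the two doses separate the two
  tails. Multiplicative lognormal reading noise (sd 0.02) and
  per-replicate growth-rate jitter (sd 0.05) emulate plate effects.

## What the generator does and does not emulate

It reproduces the statistical shape the analysis assumes: integer
zero-inflated counts with tree structure, a liability-mediated binary
trait, dose-dependent saturating growth. It does not emulate real yeast
taxonomy or genome content, horizontal transfer, lag-phase variation,
plate edge effects, or measurement dropout — so passing tests demonstrate
the pipeline's correctness and its behaviour under the modelled
conditions, not performance guarantees on any particular real dataset.
In particular, on real genomes causal and proxy families can be
arbitrarily collinear, and the generator's identifiability constraint is
exactly the assumption that real data may violate.

# Problem sizes and numerical choices

The shipped tests run the full protocol at the design scale (285 species ×
2,000 families) with 10 evaluation replicates per dataset and ten datasets
per property — a scale chosen to make the recovery and null properties
sharp while keeping a complete test run in the tens of minutes on one core.
The full-scale protocol (72,380 families, 100 replicates) is a documented
script (`scripts/reproduce_full_scale.R`) requiring an externally
obtained instance matrix. Numerical tie-breaks are deterministic
everywhere (feature index, then threshold; family identifier for ranks);
TreeSHAP equality with brute force is asserted at 1e-9; PGLS-vs-OLS at
1e-10; degenerate inputs (pure nodes, zero-variance features, zero-area
controls, empty folds) are handled by explicit rules described above
rather than by silent NaN propagation. Zero-variance features are retained
in the matrix — a forest simply never splits on them — so column sets stay
stable across subsets.

# Known limitations

* Pagel's lambda is fixed at 1; no branch-length transformation is
  estimated.
* The enrichment module does no ontology propagation; annotations must be
  pre-propagated if ancestor-term credit is wanted.
* The forest is binary-class and single-threaded by contract.
* Causal-family recovery degrades gracefully but measurably when causal
  profiles are collinear with many proxies (about one dataset in ten at
  the default design misses two of the five planted families), which is a
  property of marginal importance screens on tree-structured features,
  not of this implementation.
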