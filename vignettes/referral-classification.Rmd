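---
title: "Classifying online pharmacies by their referral links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying online pharmacies by their referral links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmref)
```

## The problem

Illicit online pharmacies (IOPs) sell prescription drugs without valid
licensing or prescriptions, and they open, close and rebrand too quickly for
manual certification lists to keep up. Certification databases cover only a
sliver of the tens of thousands of pharmacy sites on the web. `pharmref`
implements a structural screening approach: instead of inspecting a
pharmacy's own content — which its operator controls — it looks at the
*referral links* pointing at it. The working hypothesis is that a pharmacy
mostly reached from web sites that also link to known illicit pharmacies is
itself likely illicit, and that this backlink structure is hard for an
operator to manipulate wholesale.

The data structure is a sparse bipartite graph: pharmacies $i \in P$,
referring web sites $j \in W$, and backlink counts $l_{ij} \ge 1$ on the
edges (absence means zero). Ground truth is a partition of a labeled subset
of $P$ into a safe set $P_s$ (legitimate, certified) and a rogue set $P_r$
(illicit).

## The two classifiers

### RRPM: referral rating prediction

Each referrer $j$ that links to at least one labeled pharmacy gets a
*quality*

$$M_j = \frac{n_{s,j} - n_{r,j}}{n_j} \in [-1, 1],$$

where $n_{s,j}$, $n_{r,j}$ and $n_j = n_{s,j} + n_{r,j}$ count the
**distinct** legitimate, illicit and all labeled pharmacies $j$ refers to.
$M_j = 1$ means $j$ refers only to legitimate pharmacies, $M_j = -1$ only to
illicit ones. Multiplicity deliberately does not enter $M_j$: whether a
referrer links a pharmacy once or fifty times, it vouches for it either way.

A query pharmacy $i$ is then scored by the backlink-weighted mean quality of
its referrers,

$$R_i = \frac{\sum_{j \in K_i} l_{ij} M_j}{\sum_{j \in K_i} l_{ij}},$$

where $K_i$ is the set of $i$'s referrers with a fitted quality. Here
multiplicity *does* matter: many backlinks from a bad neighbourhood weigh
more than one stray link. If $i$ has backlinks but none from a known
referrer, $R_i$ is indeterminate and set to 0; if $i$ has no referral data
at all the model abstains with status `unknown` rather than guess.

The decision rule is *illicit iff $R_i < T$* (the boundary $R_i = T$ is
legitimate, following the strict inequality). Two threshold strategies are
provided:

* **conservative** (default): $T = \max\{R_i : i \in P_r \cap
  \text{training}\}$. Every illicit training pharmacy except the
  top-scoring ones falls below $T$, so sensitivity is close to 1 by
  construction and a pharmacy predicted *legitimate* is very unlikely to be
  illicit. This is the right asymmetry for consumer safety: clearing an
  illicit pharmacy is worse than flagging a legitimate one. The price is
  specificity.
* **accuracy_max**: $T$ is scanned over the unique training scores and
  their midpoints, maximizing training accuracy, with ties broken toward
  the larger (more sensitive) $T$. Because training accuracy under the rule
  $R < T$ is constant on each half-open interval between consecutive sorted
  score values and the interval's right endpoint is itself a candidate, the
  scan over consecutive values and midpoints selects the same threshold an
  exhaustive scan over all pairwise midpoints would.

### RKNN: K-nearest neighbours on backlink vectors

Each training pharmacy is a vector of raw backlink counts over the axis of
all referrers with at least one edge to a training pharmacy. A query is
projected onto that axis (its referrers unseen in training are dropped —
they add the same constant to every squared distance, so the neighbour
ranking is provably unchanged) and training pharmacies are ranked by
Euclidean distance, ties broken by ascending pharmacy identifier so results
do not depend on input order. With $K_s$ legitimate pharmacies among the
$K$ nearest, $R_x = K_s / K$ and the query is legitimate iff $R_x > 0.5$.
An even split is therefore called illicit — again the safety-first
direction. Queries without referral data abstain as `unknown`.

No scaling or log transform is applied by default, matching the raw-count
feature space; `fit_rknn(..., log1p = TRUE)` is available for heavy-tailed
data but is off by default.

## Evaluation

Illicit is the positive class throughout: *sensitivity* is the fraction of
illicit pharmacies caught, *specificity* the fraction of legitimate ones
cleared (type I error $= 1 -$ specificity, type II $= 1 -$ sensitivity),
and Cohen's kappa is chance-corrected agreement on the two decided classes.
Confusion tables are three-way — predictions and reference status each may
be `unknown`. Two conventions are implemented because they answer different
questions:

* `unknown_policy = "exclude"` (cross-validation default): abstentions are
  dropped; metrics describe the decisions the model actually makes.
* `error_rate_with_unknown()`: over reference-known pharmacies only,
  abstentions count as errors alongside misclassifications; this is the
  honest screening-deployment number, since an abstention still leaves the
  consumer unprotected.

Cross-validation uses stratified folds (per-class counts differ by at most
one across folds). With only ~50 legitimate pharmacies against ~713 illicit
ones, unstratified folds can lose the minority class entirely, which makes
specificity undefined; stratification is the only workable reading at this
imbalance. Models are refitted from scratch on each training fold —
referrer qualities, thresholds and the RKNN axis never see test-fold labels
— and fold predictions are pooled into a single confusion table by default
(per-fold averaging is available via `aggregate = "average"`; pooling is
reported because per-fold metrics are unstable when a fold holds only 5
legitimate pharmacies).

```{r cv-example}
cfg <- sim_config(seed = 42)
sim <- generate_graph(cfg)
cross_validate(sim$graph, sim$labels, "rknn", k = 2,
               n_folds = 10, seed = 42)$metrics
```

## What the synthetic generator does and does not emulate

The real referral data behind screening studies of this kind is
proprietary, so the package ships a generator that reproduces the
*structural* phenomena the classifiers exploit:

* two pharmacy classes under heavy imbalance — defaults 50 legitimate vs
  713 illicit, the scale of a real certification-list study;
* *good* referrers that link almost exclusively (`purity_good = 0.95`) to
  legitimate pharmacies and come in clusters: each good referrer belongs to
  one of `n_clusters = 5` groups sharing a pool of target pharmacies, so
  group members refer to each other's pharmacies;
* *bad* referrers that scatter: each links mostly (`purity_bad = 0.95`) to
  uniformly chosen illicit pharmacies;
* sparse integer backlink counts.

Distributional choices, made once for single-parameter simplicity: referrer
out-degree is $1 + \mathrm{Poisson}(\lambda - 1)$ with mean
`links_per_referrer = 8` *distinct* target pharmacies (out-degree counts
distinct referred pharmacies; repeated links to one pharmacy are
multiplicity, not extra targets); backlink multiplicity is geometric on
$\{1, 2, \dots\}$ with mean `multiplicity_mean = 3`, drawn once per
*referrer* and shared across its targets, because how many times a site
links each target is chiefly a property of the site's own page structure.
The referrer-level draw keeps the per-pair marginal geometric at the stated
mean while giving co-referred pharmacies similar count coordinates — which
is precisely the clustering phenomenon the Euclidean classifier relies on.
Drawing multiplicities independently per pair instead buries the
class geometry in count noise and collapses RKNN specificity far below
anything observed on real referral data, so it would defeat the generator's
purpose. Referrer counts default to 150 good vs 600 bad: illicit-pharmacy
ecosystems are sustained by large numbers of low-quality link sites.

What the generator does **not** emulate: real-world degree heavy tails
(brand pharmacies with orders of magnitude more backlinks), referrers whose
quality drifts over time, adversarial link manipulation, and sub-domain
aliasing of referrers (identifiers here are opaque and never normalized).
Passing tests on synthetic data therefore demonstrate correctness of the
methods and their qualitative behaviour under the stated structural
assumptions — not field performance on live web data.

`generate_query_set()` additionally emits unlabeled query pharmacies with a
configurable fraction lacking referral data entirely (forcing `unknown`)
and a fraction linked only to brand-new referrers (forcing the
indeterminate $R_i = 0$ path), so the abstention logic is exercised
end to end.

## Numerical and degenerate-case choices

* Distances are ranked on exact squared distances: counts are integers, so
  $|q|^2 + |t|^2 - 2\,q^\top t$ is computed exactly in doubles and ties are
  bit-reproducible across the vectorized and the naive computation.
* Kappa with degenerate marginals ($p_e = 1$, all mass in one cell both
  ways) is defined as 1 under perfect agreement and 0 otherwise, and
  flagged via `kappa_degenerate`.
* Duplicate edge-table rows are summed (referral dumps are often
  concatenated across collection runs); zero-count rows are accepted and
  dropped, since absence *is* the zero representation; negative or
  fractional counts are parse errors that name the line.
* Referrers linking only to unlabeled pharmacies get *no* quality score
  rather than a neutral default — there is no evidence either way, and a
  default of 0 would silently dilute $R_i$.
* Every stochastic step takes an explicit seed; there is no hidden global
  RNG state, and equal seeds give byte-identical output tables.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything from code:
oracle comparisons run on graphs of 20–100 pharmacies against brute-force
double loops, and the label-recovery checks run 10-fold cross-validation on
full 763-pharmacy ecosystems across 10 generator seeds. These sizes were
chosen as the smallest that exercise the study-scale imbalance (5
legitimate pharmacies per test fold) while keeping a full run of the suite
in the tens of seconds.

## Known limitations

* Both classifiers are transductive with respect to the referrer universe:
  a pharmacy reachable only through referrers absent from training is
  scored 0/indeterminate (RRPM) or ranked on an all-zero vector (RKNN).
  The `unknown` and `indeterminate` flags surface this honestly, but a
  deployment should monitor their rates.
* The conservative threshold is an order statistic of the illicit training
  scores; a single mislabeled training pharmacy with a high score can move
  it substantially. `accuracy_max` is less brittle but trades away
  sensitivity.
* Cohen's kappa is computed on decided cases only; under heavy abstention
  it describes a shrinking subpopulation.
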