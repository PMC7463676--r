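---
title: "Stratifying OGTT cohorts into metabolic footprints: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying OGTT cohorts into metabolic footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafoot)
```

## The problem and the method

Dysglycemia classification by fasting and 2 h glucose alone collapses a
multidimensional metabolic state onto one axis. `metafoot` implements a
stratification pipeline for cohorts characterised by a three-point
(0/30/120 min) oral glucose tolerance test: subjects are described by their
metabolic *milieu* (glucose, insulin, C-peptide and free fatty acids along
the OGTT, plus age, BMI and waist circumference), reduced onto a small
self-organizing map, clustered hierarchically, and each cluster is profiled
as the percentile band its median occupies in the whole cohort — its
*metabolic footprint*.

The pipeline is, in order:

1. **Exclusions** — subjects under anti-diabetes medication are removed
   first, then subjects missing any clustering variable. A subject with
   both flags counts under medication (the rules are applied sequentially;
   final membership is the complement of the union, so the order affects
   only the report, not the sample). Outliers are retained by design:
   extreme multivariate states are part of the heterogeneity the method is
   meant to expose, and the map/clustering stack is robust to them.
2. **Index panel** — every secretion, resistance, clearance, fatty-liver
   and renal index described below, computed per subject with strict
   missingness propagation (an index is `NA` exactly when an input is
   missing or its formula is undefined at the input).
3. **Feature layers** — the 15 clustering variables in five blocks of
   three: glucose, C-peptide, insulin, FFA (the three OGTT time points
   each) and anthropometry (age, BMI, waist).
4. **Multilayer SOM** — a 27-unit toroidal hexagonal map trained on the
   five layers jointly; 1000 random restarts in the full protocol, lowest
   quantization error wins.
5. **Ward clustering** of the 27 codebooks, silhouette-based selection of
   the optimal K, cuts at K = 2/11/27, bootstrap clusterwise Jaccard
   stability.
6. **Profiling** — cluster medians binned against the population's
   10th/25th/75th/90th percentiles, dysglycemia composition per cluster,
   and radar-plot footprint coordinates.

## Why 27 units

Three accepted classes of fasting glycemia times three of glucose
tolerance times three OGTT time points give 27 combinations; the map's
27 units give the dendrogram a leaf per combination-scale microcluster
while still being far coarser than the cohort, which is what makes the
unit-level dendrogram readable.

## Scaling and layer balance

Only BMI and waist are min–max scaled, *within gender* (their reference
distributions differ by sex); age and the twelve OGTT variables are
z-standardized. Raw insulin spans hundreds of pmol/L while FFA stays below
about 1.5 mmol/L, so unstandardized Euclidean distances would be an
insulin metric. On top of the per-variable standardization, the map
normalizes each layer's squared distance by its data-wide mean (the sum of
the layer's column variances) before summing, so all five layers
contribute comparably to the best-matching-unit criterion regardless of
block scale. Ward clustering and silhouette computation operate in that
same weighted metric (each layer multiplied by the square root of its
weight), so the tree sees exactly the geometry the map was trained in.

## SOM details and their rationale

* **Grid**: 3 × 9 hexagonal, toroidal. 27 is odd in both factorizations
  (3 × 9 or 1 × 27), and a perfect hexagonal torus needs even dimensions,
  so the vertical wrap has a *seam*: outer-row units meet their wrap
  partner at distance √3/2 instead of 1. This is accepted and documented;
  the layout is configurable. The seam slightly over-connects the outer
  rows, which only matters for the Gaussian neighborhood and vanishes as
  the radius shrinks.
* **Schedule**: learning rate linear 0.05 → 0.01; neighborhood radius
  linear from the 67th percentile of inter-unit distances ("two thirds of
  the units") to 0 at the last step; Gaussian neighborhood, updates with
  factor below 1e-12 skipped. One "iteration" is one pass over the data in
  a freshly randomized order (500 passes by default).
* **Initialization**: codebooks sampled from distinct subjects; every run
  fully determined by its seed; restarts use consecutive seeds so a larger
  restart budget nests the smaller one and the selected quantization error
  is non-increasing in the budget.
* **Degenerate limit**: with radius 0 the update touches only the BMU and
  the algorithm is online k-means; the test suite holds this path against
  an independent k-means oracle. One caveat found while testing: 27
  mutually distant *random* points are only claimed one-to-one by the 27
  units in this vector-quantization limit. With the wide default initial
  radius, units get topologically trapped (random points have no toroidal
  arrangement) and the trained map typically claims about 20 of 27 units
  on such data. On realistic cohort data, which the map unfolds on a
  low-dimensional manifold, this is not a practical concern, but it is why
  the "one unit per point" property is asserted at small radius only.

## The index panel

All concentrations follow one package-wide convention (glucose mmol/L,
insulin pmol/L, C-peptide nmol/L, FFA mmol/L, lipids and creatinine
mg/dL); conversions (glucose ×18.016 to mg/dL, insulin ÷6.0 to mIU/L) are
applied inside formulas that demand them, and every index is invariant to
declaring insulin inputs in mIU/L instead.

* AUCs: trapezoidal over 0–30–120 min, in native unit × min.
* Secretion: absorptive ratios `(C0+C30)/(G0+G30)` and `(I0+I30)/(G0+G30)`;
  IGI `(I30−I0)/(G30−G0)`; the C-peptide analogue; DI = IGI/I0. When
  G30 = G0 the difference quotients are undefined and flagged `NA` rather
  than allowed to blow up; they then drop out of cluster medians.
* HOMA: the second-generation indexes come from a closed-source iterative
  calculator that cannot be reproduced from its description, so the
  package's default backend is the classic closed form (IR =
  G0·I0[mIU/L]/22.5; B = 20·I/(G0−3.5)), with fasting C-peptide converted
  to an insulin-equivalent (10.6 mIU/L per nmol/L, the cohort-typical
  fasting molar ratio) for the beta-cell index, which the reference
  computation bases on C-peptide. This is explicitly an *approximation on
  a different scale* — the closed form at typical normometabolic inputs
  gives ≈1.74 (the test suite computes this), roughly twice the scale the
  iterative calculator reports for comparable inputs; a pluggable backend
  accepts precomputed calculator values unchanged. Whether the
  resistance index should use insulin or C-peptide is not documented
  upstream; the default uses insulin.
* Matsuda: `10000/√(G0·I0·Ḡ·Ī)` with the means over the three available
  time points and the conversions above.
* Tissue-specific: Liver-IR (logs base 10, configurable), Hepatic-IR as
  the product of the 0–30 min insulin and glucose trapezoids in native
  units, Adipo-IR = FFA0·I0, and ISI-FFA = 2/(AUCins·AUCffa + 1). The
  ISI-FFA product is scale-sensitive and its source gives no units; the
  package scales the insulin AUC by 1e4 and the FFA AUC by 30 so the
  product is O(1) and the index spans (0, 2]. Both constants are exposed
  as arguments.
* Insulin clearance: C-peptide/insulin ratios at fast, 0–30 and 30–120 min
  (single-interval AUC ratios collapse to sum ratios), and the 0–30 min
  *suppression* slope `(IC_fast − IC30)/30` — positive when clearance
  falls after the load, matching the sign convention of the published
  population medians.
* Fatty liver: NAFLD-FLS (with the metabolic-syndrome and diabetes flags
  and insulin in mIU/L) and FLI (logistic of TG, BMI, waist; bounded in
  [0, 100]). The metabolic-syndrome flag follows the IDF definition
  (sex-specific waist, TG, HDL, BP or unavailable-as-false, fasting
  glucose ≥ 5.6 mmol/L).
* eGFR: CKD-EPI 2009 creatinine equation, sex-specific knots, race
  coefficient omitted (single-origin cohort, no race variable).
* Dysglycemia: WHO 1999 bands (IFG from 6.1 mmol/L, not the ADA 5.6),
  diabetes at G0 ≥ 7.0 or G120 ≥ 11.1, boundary values inclusive.

## Clustering choices

Ward linkage is the Ward.D2 variant (merge minimizing the increase in
within-cluster variance on Euclidean distances; heights √(2·ΔSSE)) — the
recommended usage of the implementation the original analysis cites, and
oracle-tested here against a brute-force minimum-ΔSSE agglomerator. The
silhouette is computed on the 27 *units* (codebook vectors), matching the
scale at which the optimal K is defined; a subject-level silhouette would
mix map quantization into the model-selection criterion. Singleton
clusters score silhouette 0 by the usual convention. Ties in the argmax
resolve to the smallest K.

Stability follows the clusterwise-Jaccard methodology: each bootstrap
resample reruns scaling, map training (10 restarts by default — selection
noise is part of what stability should absorb) and the Ward cut; each
original cluster is matched to its maximum-Jaccard resample cluster over
the subjects common to both; values are averaged per cluster and then
unweighted across clusters. A resample yielding fewer than K non-empty
clusters is skipped and logged. Units with no mapped subjects keep their
codebooks in the 27-leaf tree but contribute nothing to subject partitions.

## Profiling choices

Percentiles use linear interpolation between order statistics (the default
of most statistical environments). A cluster median exactly on a
percentile boundary resolves *toward the middle bin* — the 25th–75th band
is read as "the accepted normal range", so boundary values are not
pathologized. The footprint radius maps the five bins to
{0, 0.25, 0.5, 0.75, 1} and reverses variables whose adverse direction is
low (insulin sensitivity, secretion capacity, clearance levels, eGFR,
HDL-c), so a larger radius is always "more adverse". The grouping into
milieu/mechanisms/pathology and the direction flags are declarative
tables; the shipped defaults live in `extdata/` and can be replaced per
call.

## The synthetic cohort generator

No subject-level data from the motivating survey is public, so the
generator *is* the test bed. It emulates: a mixture of metabolic
archetypes (normometabolic — centred on the published population medians —
insulin-resistant/hyperinsulinemic, insulin-deficient with high clearance,
hyperinsulinemic with low clearance); log-normal concentration marginals
(positive, right-skewed, as population tables show) parameterised so the
stated central value is the exact marginal *median*; AR(1)-like serial
correlation (ρ = 0.6 adjacent, ρ² across) between the three OGTT time
points of each analyte on the log scale; truncated-normal anthropometrics
with BMI–waist correlation 0.8 and weight derived from BMI and height so
the BMI identity is exact; 60% women; and per-subject missingness (5.7%)
and medication flags (5.3%) at the survey's observed exclusion rates.

It does **not** emulate: assay error structure, medication effects on the
measured values (flagged subjects are metabolically unremarkable),
intra-archetype covariance beyond the OGTT blocks and BMI–waist,
longitudinal drift, or autoimmune/genetic variables. A green recovery test
therefore establishes that the pipeline finds planted mixture structure of
the stated separation at the stated n — not that any particular clinical
cohort has such structure.

The planted two-cluster world used by the acceptance checks mixes the
normometabolic and insulin-resistant archetypes 50:50 with the
insulin-resistant centre moved along the line between the two centres so
the fasting-insulin means sit exactly 3 pooled SDs apart (SD read as
cv·median on the raw scale, cv = 0.35). Three was chosen because it is the
stated minimum of the recovery setting; it was fixed before any downstream
result was measured.

## Numerical and degenerate-input policy

* Zero glucose excursion, non-positive log arguments, zero insulin, G0 at
  or below the HOMA-B knee: flagged `NA`, never infinity; a panel on any
  generated cohort contains no infinite value.
* Constant clustering variables or a single-subject gender group make
  scaling impossible and fail fast with a named error.
* Scaling parameters round-trip (transform then inverse) to 1e-12.
* All randomness flows through explicit integer seeds; reruns are
  byte-identical, including written artifacts (the run manifest records
  md5 hashes and no timestamps).

## Known limitations

* The HOMA backend is a first-generation closed form on a different scale
  from the second-generation calculator values it stands in for; compare
  trends, not levels, unless you plug in calculator output.
* The hexagonal torus has a geometric seam in any 27-unit layout.
* ISI-FFA and Hepatic-IR magnitudes depend on unit-scale constants that
  their sources leave unstated; both are configurable and documented.
* Bootstrap stability reruns use a reduced restart budget by default
  (10 vs 1000); the full protocol is one flag away but desk-scale runtime
  was prioritised, and the stability statistic is designed to absorb
  exactly this selection noise.
* Fat-mass % (needed by Liver-IR) is generated directly rather than
  derived from anthropometry, since its provenance in the motivating
  survey is unstated; blood pressure likewise exists mainly so the
  metabolic-syndrome flag is computable.
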