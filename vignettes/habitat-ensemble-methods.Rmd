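---
title: "Evaluating and combining pre-existing habitat suitability models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and combining pre-existing habitat suitability models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmeval)
```

## The problem

Land-management agencies frequently inherit several habitat-suitability
models for the same rare species, delivered by different modelling groups
("contractors") with different occurrence data, covariates, algorithms,
extents, resolutions, and — critically — different and often poorly justified
suitability thresholds. Before such models can support land-use decisions,
two questions must be answered: *which models are defensible enough to use*,
and *how should their continuous surfaces be converted into one categorical
map*?

`hsmeval` implements a two-pronged answer:

1. **A construction audit.** Each model is rated against a fixed rubric of
   23 topics in five categories (occurrence data, environmental covariates,
   modelling algorithm, extent and resolution, model selection and
   thresholds). Three occurrence-data topics carry hard *exclusion gates*;
   only models passing all three are "acceptable" for mapping probable
   suitable habitat.
2. **A performance evaluation.** Model output is scored by its *capture
   rate* — the fraction of quality-controlled, spatially thinned evaluation
   occurrences falling in pixels classified suitable — and thresholds are
   recalibrated so every contributing model, and the final union map, meet
   explicit capture-rate requirements.

Models passing both prongs are unioned into a **probable suitable habitat**
product; the remainder form a complementary **potential suitable habitat**
product intended only to target future field surveys.

## Occurrence quality control

Evaluation occurrences are element-occurrence *polygons* with an ordinal
accuracy class (1–10), a record year, and an occurrence rank.

* **Window.** Records are filtered to the model-building period
  (default 1981–2012, inclusive). Later records (2013–2018 by default in the
  generator) are reserved as an independent validation set.
* **Precision.** Classes 1, 2 and 4 are precise at any polygon size; class 3
  is precise only when the polygon is no larger than a circle of radius
  150 m, operationalized on the equivalent radius `sqrt(area / pi)`. All
  other classes are dropped.
* **Internal centroid.** Each polygon is reduced to a representative point
  that is guaranteed to lie inside it: the geometric centroid when that is
  interior, otherwise the midpoint of the widest interior chord on a
  horizontal scan line (starting at the median vertex y, then at y
  quantiles). The construction is deterministic.
* **Spatial thinning.** The evaluation set is the *largest possible* subset
  of centroids with pairwise separation of at least 430 m. This is a maximum
  independent set problem on the distance graph and is NP-hard in general,
  so `thin_maximal()` offers two modes. The default heuristic runs a seeded
  randomized greedy (random candidate order, keep-if-feasible) with 100
  restarts plus one deterministic pass in `record_id` order, returning the
  best subset found; results are bit-identical for a fixed seed, always
  respect the separation bound, and are always maximal. The exact mode
  (branch and bound per connected component of the conflict graph, permitted
  for up to 15 points) returns a maximum-cardinality subset and backs the
  test-suite oracle comparisons.

Distances are planar Euclidean in a projected metre CRS. Geographic
(degree-unit) input must be projected first; the built-in projection is a
local equirectangular tangent plane with ellipsoidal scale factors, adequate
for working windows of tens of kilometres (area error well below 0.5%).

## The audit rubric and its gates

The three gated topics are computed from the records available for the
model-building window (before thinning, since they judge the data a model
was *built* from):

| Gate | Fails when | Rating levels |
|---|---|---|
| Number | fewer than 10 occurrences | ideal > 50; acceptable 25–50; else caution |
| Age | more than half the records date from 1950 or earlier | ideal: all ≥ 2000; caution: > 20% ≤ 1980; else acceptable |
| Accuracy | more than half the records have classes 6–10 | ideal: all precise; acceptable: ≥ 80% precise; else caution |

Reading the quantifiers: "majority" is strictly more than 50%, "substantial
portion" strictly more than 20%, "most" at least 80%. A documented
small-range override (`small_range_flag`) lets fewer than 25 occurrences
rate `acceptable` for species with very small, well-understood ranges; it
never affects the gate.

The remaining 20 topics are judgement calls about contractor reports that no
program can parse; they are supplied as an evidence config (YAML/JSON,
topic key → rating + note) and *default to "interpret with caution"* when no
evidence is given — absence of documentation is itself a finding. The rubric
never aggregates ratings into a score: only the three gates decide
acceptability.

## Threshold recalibration

A pixel is suitable when its value is *greater than or equal to* the
threshold; the closed comparison reproduces a contractor's above-threshold
footprint exactly at the delivered threshold. Capture rates use all
evaluation points in the denominator — points outside a model's extent or on
nodata count against it, the strict reading of how partial-extent models
should be penalized.

Candidate thresholds are the model's values sampled at the evaluation
points: the capture rate only changes there, making calibration exact and
cheap. Because the rate is non-increasing in the threshold:

* `at_least` mode returns the **largest** threshold whose rate meets the
  target — which also attains the smallest achievable rate at or above the
  target, so the "approximately the target, never below" reading
  (`closest_above`) selects the same threshold; both names are accepted.
* `closest` mode minimizes `|rate − target|` with ties resolved upward, used
  where a product must get *as close as possible* to a target.

Models delivered only above their threshold can never be lowered: if the
delivered footprint captures less than the target, the model is *ineligible*
for the probable boundary (it may still be overlaid inside the boundary and
mapped as potential habitat).

Per-model targets default to 0.80, relaxed to 0.78 for contractors whose
modelling style cannot match capture rates closely (`capture_target` on the
model). Scores are standardized per model to the 1–100 scale by the linear
map `s = 1 + 99 (x − min) / (max − min)` over valid pixels (a constant
surface maps to 100); the map is invariant to positive affine transforms of
the input.

## Building the products

**Probable suitable habitat.** Acceptable models that meet (or are
recalibrated to) their per-model target form the *qualifying set*; the outer
boundary is the union of their binary maps. If the union captures less than
the boundary target — 0.90, relaxed to 0.89 when a relaxed-target model is
in the union — thresholds of lowerable (full-surface) qualifying models are
decreased by a greedy rule: repeatedly take the uncaptured evaluation point
whose maximum suitability across lowerable models is highest, lower that
model's threshold to that value, and recompute. The rule is deterministic,
moves thresholds minimally, and each step provably enlarges (never shrinks)
the union; the loop stops at the target or when no lowering remains, in
which case the product is returned flagged non-compliant with a warning.
With exactly one qualifying model, its threshold is instead set as close to
the boundary target as possible (`closest` mode).

Inside the boundary, *all* acceptable models — including those that failed
per-model calibration — are overlaid at their thresholds, giving a per-pixel
model count and a per-pixel mean standardized score. Masked model variants
are preferred for this product; a water mask, when supplied, is applied
before capture statistics. Developed land cover is deliberately *reported,
never masked*: developed-classified pixels regularly contain real
occurrences, so masking would discard habitat.

The per-pixel mean is ambiguous between two readings: average over all
acceptable models valid at the pixel (default, `score_average =
"all_valid"`), or only over models predicting suitable there
(`"suitable_only"`). Both are implemented behind the switch; neither is
claimed to be the canonical choice.

**Potential suitable habitat.** Models not used for the boundary — gate
failures and calibration failures — with unmasked variants substituted for
masked deliveries, each thresholded as close to 0.80 as possible (delivered
thresholds kept when recalibration is impossible), unioned, and clipped to
outside the probable boundary. Probable and potential are disjoint by
construction.

Products are emitted on the common grid (default: the finest native input
resolution, nearest-neighbour resampled so no contractor's values are
invented or lost) with a manifest note recommending use at no finer a
resolution than the coarsest contributing model. A multispecies stack counts
species per pixel, and area summaries report km² and acres
(1 m² = 0.000247105381 acres) in total and within arbitrary, possibly
overlapping, management overlays.

## The synthetic-data generator

Real contractor rasters and natural-heritage occurrence records are
proprietary, so the generator emulates their structure end to end:

* smooth spatially autocorrelated covariates (Gaussian-smoothed white noise,
  ~1 km correlation length) and a truth suitability surface that is a
  logistic function of a covariate combination, hence strictly in (0, 1);
* occurrence centres drawn with probability proportional to truth, buffered
  into circular polygons whose radii bracket the 150 m rule from both sides
  by accuracy class (1, 2, 4: well under; 3: 50–400 m; 6–10: far over),
  with years and ranks drawn from configurable mixes;
* contractor models: truth degraded by smooth noise, block-averaged to each
  style's resolution, optionally clipped to synthetic 2-km "watersheds"
  containing occurrences (masked variants) or truncated to
  values-above-threshold-only deliveries.

Everything is integer-seeded and bit-reproducible. The default study
conditions are a 10 km × 10 km window at 100 m truth resolution, 150
occurrences, three full-surface contractor models (100/300/200 m, noise SD
0.05/0.15/0.10), and 60 thinned evaluation points — sizes chosen so a full
pipeline run takes seconds while leaving dozens of independent 430-m-spaced
points and multi-thousand-pixel products. The extended style set adds a
masked/unmasked pair (with the relaxed 0.78 target) and an
above-threshold-only delivery, so a generated workspace exercises every
eligibility branch.

What the generator does *not* emulate: irregular real occurrence polygons
(circles suffice because only area and containment matter downstream),
ecological realism in covariates, spatial survey bias, and taxonomic error.
Passing tests therefore demonstrate the *procedural* guarantees — gates,
separation, calibration, union capture, disjointness — not predictive skill
on real landscapes.

## Numerical choices and edge cases

* Ties in the deterministic greedy pass are broken by `record_id`
  lexicographic order; all stochastic steps take explicit integer seeds and
  restore the caller's RNG state.
* Suitability comparisons are closed (`>=`); evaluation points on the exact
  eastern/southern grid edge belong to the last pixel.
* Empty record sets filter to empty (not an error); an empty evaluation set
  makes capture rates undefined (an error); an all-nodata surface cannot be
  standardized (an error).
* Degenerate polygons (zero area) are rejected; constant-valued models
  standardize to 100 everywhere valid.
* "No acceptable model" and "no qualifying model" are signalled as classed
  conditions (`hsmeval_no_acceptable_model`, `hsmeval_no_qualifying_model`,
  both inheriting `hsmeval_product_unavailable`) so pipelines and the CLI
  can distinguish an honest "no probable map for this species" from a hard
  error.

## Interfaces and formats

The package deliberately carries no compiled geospatial dependency: rasters
exchange as ESRI ASCII grids (`read_asc()` / `write_asc()`), vectors as
GeoJSON (`read_geojson()` / `write_geojson()`), and reports as CSV,
Markdown, and JSON manifests. A thin command-line wrapper
(`system.file("cli", "hsmeval.R", package = "hsmeval")`) exposes
`simulate`, `evaluate`, `calibrate`, `probable`, `potential`, `stack`, and
`areas` subcommands over these files.

## A compact worked run

```{r worked, eval = FALSE}
cfg <- synthetic_species_config(seed = 1)
inputs <- simulate_species_inputs(cfg, n_eval_points = 60)
evidence <- setNames(
  as.list(rep("acceptable", 20)),
  rubric_topics()$topic[!rubric_topics()$computed])
rubrics <- lapply(inputs$models, function(m)
  evaluate_model(m$model_id, inputs$eval_records, evidence = evidence))
probable <- build_probable(inputs$models, rubrics, inputs$eval_points,
                           species = cfg$species,
                           independent_points = inputs$independent_points)
probable
```

On these conditions the union boundary captures 90% of the 60 evaluation
points (54/60), 92.9% of the independent 2013–2018 points, and covers
80.8 km²; per-pixel mean standardized scores stay within [1, 100] by
construction. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* All geometry is planar; inputs must share (or be projected to) a metre
  CRS. The built-in tangent-plane projection targets desk-scale windows,
  not continental extents.
* The audit's 20 qualitative topics are only as good as the evidence config;
  the package enforces the caution-by-default rule but cannot read reports.
* The greedy boundary-lowering rule is one defensible operationalization of
  "decrease thresholds until the union meets the requirement"; it is
  deterministic and minimal-movement, but not claimed unique.
* Heuristic thinning is near-optimal in practice (and provably no worse than
  a single greedy pass) but only the exact mode guarantees maximum
  cardinality, and only for small n.
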