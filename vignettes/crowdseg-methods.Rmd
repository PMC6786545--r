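---
title: "Methods: consensus evaluation of crowd-sourced segmentations"
author: "crowdseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus evaluation of crowd-sourced segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdseg)
```

`crowdseg` evaluates panels of annotators who outline an anatomical
structure on medical images by clicking ordered boundary points. This
vignette is the package's account of the methods: the geometric and
statistical conventions it commits to, why, and what its validation on
synthetic data does and does not establish about real annotation data.

## From outlines to masks

An annotation is an ordered vertex list in continuous image coordinates,
implicitly closed. The package converts it to a pixel mask by a scanline
fill under the even-odd rule, with these conventions:

- **Pixel centres.** Pixel indices are 0-based and the centre of pixel
  (row `r`, col `c`) is at `(x, y) = (c + 0.5, r + 0.5)`. A pixel
  belongs to the segment iff its centre is strictly inside the polygon.
- **Half-open edges.** For a scanline through `y`, an edge spanning
  `[min(y1, y2), max(y1, y2))` is counted once — for the endpoint with
  the smaller `y` only. Together with the strict `x` comparison this
  means a centre lying exactly on an edge is *outside*, and two
  polygons sharing an edge tile the grid with no pixel counted twice.
  Annotation tools that report integer vertex coordinates routinely
  produce such exact hits, so the tie rule is load-bearing, not an
  edge case.
- **Clipping.** Polygon parts outside the grid are clipped; a polygon
  fully outside yields an empty mask.
- **Degenerate input.** Fewer than three vertices is an error; three or
  more collinear vertices (zero area) yields an empty mask with a
  warning. Self-intersecting polygons — plausible output of hasty
  annotators — are accepted and filled under even-odd semantics rather
  than rejected.
- **Multiple regions** in one record are merged by set union. Holes are
  therefore not representable; nothing in point-outline annotation
  workflows suggests annotators intend holes, and a non-goal is better
  than a silent misinterpretation.

The even-odd/centre/half-open combination was chosen because it admits
an unambiguous independent oracle — a brute-force point-in-polygon test
at every pixel centre — against which the scanline fill is verified
exhaustively in the test suite (hundreds of random star-shaped polygons
on grids up to 64×64, plus adversarial axis-aligned and
self-intersecting cases). Whether the original tooling of any given
study counted boundary pixels or used centres is generally unknowable;
the convention here is a documented choice, not an inference.

All geometry is in pixel units. Physical pixel spacing (e.g. an MR
in-slice resolution of 0.49 mm) is carried on the `image_grid` as
metadata only; no reported metric is mm-denominated.

## Consensus by majority vote

For one image, the consensus map holds at each pixel the fraction of
that image's annotators whose mask includes it. Two decisions matter:

- **Per-image denominator.** Citizens segment random subsets of the
  dataset, so "more than half the citizens" is read as more than half
  of the citizens *who segmented that image*. Using the full panel
  roster as denominator would make consensus unattainable on sparsely
  covered images. Images covered by fewer than `min_coverage`
  annotators (default 3) are flagged in the coverage table but still
  processed.
- **Strict threshold.** The consensus segmentation at threshold `t`
  keeps pixels with fraction strictly greater than `t`. At the default
  `t = 0.5` this is the majority vote; with a 3-expert panel it means
  at least 2 of 3, and with an even panel an exact 50/50 split is
  excluded. Strictness also forces the nesting property — the
  0.75-segment is a subset of the 0.5-segment is a subset of the
  0.25-segment — which the suite asserts on every synthetic consensus
  map it builds. Thresholds 0.25 and 0.75 are first-class citizens
  because the standard sensitivity analysis re-runs the whole
  comparison at them.

More sophisticated fusion (STAPLE-style weighting of annotators by
estimated reliability) is deliberately out of scope: the evaluation
target is the plain majority vote.

**Duplicates.** An annotator may re-segment an image in a later
session. Repeats count toward throughput (they are work done) but are
excluded from every accuracy analysis, keeping the earliest-session
record; records without a session number rank after numbered ones. The
pipeline reports the number removed.

## Scoring

Agreement between masks A and B is the Dice similarity coefficient
`2|A∩B| / (|A|+|B|)`. Conventions:

- Two empty masks score 1; an empty mask against a non-empty one scores
  0. Real data never hits this; degenerate synthetic cases stay
  defined, and the convention is stated here rather than buried.
- Dice relates to the Jaccard index by `D = 2J/(1+J)`; the suite uses
  an independently computed Jaccard as a cross-check on random masks.

The analyses mirror the standard study structure: each individual
subject-annotator against the per-image reference consensus (expert
consensus as working ground truth); subject consensus against reference
consensus per image; and all pairwise Dice within the reference panel
(its internal agreement, the yardstick for the subject consensus).
Summary statistics follow the "median citizen accuracy" convention:
within each image, the median over individuals; then mean/SD of those
per-image medians across images.

**Leave-one-out.** When a scored annotator is also part of the
reference panel their own mask inflates the reference. The default is
*no* leave-one-out correction, because the headline comparison (citizens
vs expert consensus) has disjoint panels and the issue does not arise;
`score_individuals(leave_one_out = TRUE)` rebuilds the reference
without the scored annotator for self-referential designs.

## Annotator statistics

- **Throughput.** Per-annotator image counts per session, compared
  between consecutive sessions with a two-sided Mann-Whitney U test.
  Ties get midranks; U is reported for the first sample under the
  rank-sum convention `U = R_a − n_a(n_a+1)/2`. With both samples of
  size ≤ 8 the p-value is computed by full enumeration of the
  permutation null (exact even under ties, since the label-swap
  symmetry of U about `n_a n_b / 2` survives midranks); larger samples
  use the normal approximation with tie correction and a 0.5 continuity
  correction. Published one-off U statistics rarely state their
  convention (sidedness, tie handling); two-sided with midranks is
  adopted here as the defensible default and stated rather than
  guessed. Sessions with lost data are absent from the table, never
  zero.
- **Point budget vs workload.** Pearson product-moment correlation
  between each annotator's mean outline points per image and the total
  images analysed, two-sided t-test on n−2 degrees of freedom. Zero
  variance in either variable is an explicit error, not an NA.
- **Age vs accuracy.** Pearson correlation between age and the
  annotator's median Dice against the reference consensus — the
  per-annotator accuracy summary — plus the least-squares slope
  rescaled to Dice per decade. Which per-annotator summary a published
  age correlation used is often unstated; the median-Dice choice is
  documented here.

## The synthetic study generator

No public corpus of point-outline panels with ground truth exists at
the scale needed, so validation rests on a generator whose defaults
encode a realistic study: 150 images; 29 citizens each segmenting a
truncated-normal 85 ± 43 of them (bounds [1, 150]); 3 experts
segmenting everything; per-annotator point budgets uniform on 36–130.

**Shapes.** Each image's ground truth is a vertebra-like figure: a
star-shaped body whose centre-to-boundary distance is an
anisotropically scaled radius with low-frequency cosine modulation
(radius 18–26% of the grid, anisotropy 0.85–1.2, modulation amplitudes
≤ 0.08), plus a thin posterior process — a 3–5 px wide strip extending
about half a body radius downward. The contrast matters: agreement is
systematically lower on small thin structures than on large round
ones, and the generator must reproduce that for the evaluation to be
exercised honestly. The default grid is 96×96 px, large enough for a
~40 px body with realistic boundary noise while keeping a full 150-image,
32-annotator study under half a minute to simulate and rasterize.

**Annotator noise.** An annotator samples their point budget
arc-length-uniformly along the true boundary (split between body and
process by perimeter share, with a random phase) and displaces each
point by `bias + N(0, sigma)` pixels — *radially from the centroid* for
the body, which keeps outlines of star-shaped bodies simple polygons
and makes the planted sigma exactly recoverable from radial residuals;
*along the local outward normal* for the thin process, where a radial
model is meaningless. With probability `gross_error_rate` the outline
is instead drawn around a displaced (0.3–0.6 radii), 0.6×-shrunken
body — the occasional annotator who outlines the wrong thing. Defaults:
experts sigma 0.5–1 px, zero bias, no gross errors; citizens sigma
0.8–2.8 px, bias within ±0.5 px, 2% gross errors. These were chosen
once so the emergent statistics land where human panels land on this
kind of task — most individual citizens above 0.8 Dice against the
expert consensus, citizen medians around 0.9, expert pairwise agreement
around 0.95 — and are not claims about any particular cohort.

**Workload coupling.** Annotators who place many points work more
slowly and get through fewer images; empirically this shows up as a
strong negative correlation between point budget and images analysed.
Workloads are therefore drawn through a Gaussian copula linking the
annotator's point-budget rank to their workload quantile (latent
correlation −0.675 by default), which plants the behavioural trend
while leaving the truncated-normal workload marginal exactly as
configured — the suite checks both the marginal moments (against the
closed-form truncated-normal mean and SD) and the induced correlation.

**Ages.** Synthetic citizen ages are uniform on 18–73. By default age
and skill are independent; `plant_age_effect = TRUE` makes sigma
increase with age so the age–accuracy regression has a recoverable
planted truth. The slope-recovery validation uses directly simulated
per-annotator summaries (planted −0.005 Dice/decade, observation noise
SD 0.002, n = 29) because that isolates the estimator from the
generator.

**Seeding.** All randomness flows from one top-level design seed
through named substreams (shapes, models, assignment, one per outline),
derived by a small modular hash kept below 2^31. Any stage can be
regenerated independently; two runs from the same seed are
byte-identical.

**What the generator does not emulate.** Image intensities (annotators
see no image; their errors are purely geometric); learning effects
across sessions (the session split is a fixed proportion, slightly
lighter in session 1); correlated errors between annotators (all noise
is independent given the shape — real annotators share systematic
confusions, which majority voting handles *worse* than independent
noise); non-star-shaped bodies; and pathology or anatomical variants.
Passing the synthetic validation therefore establishes that the
pipeline's arithmetic and contracts are correct and that majority
voting behaves as theory predicts under independent noise — not that
any particular human panel will reach any particular Dice.

## Validation at study scale

The test suite exercises, among others:

- scanline-vs-brute-force equivalence on 200+ random simple polygons
  (grids ≤ 64×64), translation equivariance, tiling without double
  cover;
- Dice algebra (identity, symmetry, the IoU relation) on 1000 random
  mask pairs, plus hand-counted fixtures;
- threshold nesting on every consensus map of a simulated study;
- the majority-vote benefit at full default scale (150 images, 29
  heterogeneous citizens): the per-image citizen-consensus Dice against
  ground truth exceeds the per-image median individual Dice on at least
  90% of images;
- recovery of planted annotator sigma within 15% relative error from 30
  outlines per annotator, and of a planted −0.005 Dice/decade age slope
  within ±0.002;
- Mann-Whitney agreement with full null enumeration for all sample-size
  pairs up to 6, tied and untied;
- the duplicate-handling contract (throughput counts repeats, accuracy
  excludes them, earliest session wins).

The full-scale blocks run in well under a minute each; smaller unit
fixtures (12-image studies on 64×64 grids) keep the rest of the suite
fast without weakening the full-scale checks.

## Numerical and degenerate-input choices

- Collinearity of a polygon is tested against a tolerance of 1e-9
  scaled by the coordinate magnitude.
- `findInterval` on sorted crossings implements the strict "crossings
  to the right" parity count without per-pixel floating-point
  subtraction.
- Exact Mann-Whitney comparisons use a 1e-9 slack when comparing
  |U − μ| values, so midrank arithmetic cannot flip a tie in the null
  enumeration.
- Empty mask lists, mismatched grids, thresholds outside (0, 1), empty
  samples, zero-variance correlations and all-degenerate records are
  errors; single degenerate regions and low-coverage images are
  warnings/flags. The pipeline skips malformed annotation rows with a
  per-row log and aborts if more than a configurable fraction (default
  5%) is malformed.

## Limitations

Surface-distance metrics (Hausdorff, mean contour distance),
multi-slice volumetric Dice, probabilistic label fusion, and polygon
holes are out of scope. The consensus of a panel whose members share
systematic bias converges on that bias; majority voting corrects
independent error only, and nothing in the Dice-against-consensus
framework can detect a collectively wrong panel.
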