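---
title: "Quantifying the extent of retinal vascularization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the extent of retinal vascularization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervquant)
```

## The measurement problem

Retinopathy of prematurity (ROP) is classified by *zone*: how far the
developing retinal vasculature has advanced from the optic disc toward the
periphery, judged subjectively from fundus photographs or indirect
ophthalmoscopy. The judgement is famously variable between observers.
`ervquant` implements a continuous, pixel-based alternative: the **extent of
retinal vascularization (ERV)**, the Euclidean distance from the optic-disc
centroid to the vascular–avascular junction (the visible "stage" line),
measured separately in the nasal (NERV) and temporal (TERV) fields of view.
Per image the minimum and mean of the radial profile are retained; per eye,
the minimum across images per side.

All quantities are in pixels. No pixel-to-millimetre conversion is
attempted: such conversions depend on axial length, which can only be
estimated at these ages, and on assumptions about retinal curvature.
Coordinates are 0-based, origin top-left, x rightward (columns), y downward
(rows), with pixel centres at integer coordinates — the dominant raster
convention.

## From clicks to a measurement

A grader clicks an unordered set of points along the visible stage line.
The pipeline is:

1. **Ordering** (`order_points_greedy`). A greedy open tour: always connect
   to the nearest unvisited point. The tour is restarted from *every*
   candidate start point and the shortest total path is kept. A fixed
   start (e.g., the first click) would make the result depend on click
   order, which is arbitrary; the multi-start rule removes that artifact
   while preserving the greedy nearest-neighbour construction. Ties are
   broken deterministically (lowest start index, then lowest point index).
   Greedy ordering is exact on convex, well-sampled arcs — the geometry of
   a ridge line clicked at reasonable density — and the property suite
   checks it never beats the exhaustive optimum.
2. **Smoothing** (`fit_smooth_path`). A parametric cubic spline in chordal
   parameterisation is *interpolated* through the ordered clicks (natural
   boundary conditions; smoothing factor zero) and resampled at 1 px
   arc-length spacing. We read "smoothed using spline interpolation" at
   face value: the spline interpolates, and click noise is the grader's
   responsibility, not the fit's. With 2 or 3 points the path degrades to
   the linear/low-order curve. Resampling at pixel resolution makes the
   subsequent minimum and mean behave like statistics over "each pixel of
   the segmented stage" rather than over the arbitrary click locations.
3. **Disc localization** (`disc_centroid`). The disc centre is the centroid
   (mean pixel-centre coordinate) of the disc segmentation mask; if a mask
   has several connected components the largest is used. A known centroid
   can be supplied directly (`disc_from_centroid`) since disc detection
   itself is upstream of this package.
4. **Radial profile and summary** (`radial_profile`, `summarize_erv`).
   Per-vertex Euclidean distance to the disc centroid; the minimum (first
   vertex on exact ties), the vertex-uniform mean (arc-length weighted by
   construction of the resampling), the location of the minimum, and — when
   a fovea coordinate is available — the *meridian angle*: the signed angle
   at the disc centre between the disc→fovea ray and the disc→minimum ray,
   in (−180°, 180°], positive counterclockwise in image coordinates.
5. **Notches** (`detect_notches`). A notch is a localized posterior
   incursion of the junction: a local minimum of the profile more than
   `depth_threshold` (default 20 px) below the running median over a
   window of 1/8 of the path length. Symmetric local maxima are *reverse*
   notches; two qualifying dips are a *double* notch. Non-maximum
   suppression within one window prevents click noise from splitting one
   notch into several. The 20 px / (1/8) defaults are package choices:
   deep enough to ignore click jitter and smooth modulation, local enough
   that a notch does not contaminate its own baseline.

Numerical edge cases are handled explicitly: duplicate consecutive clicks
are dropped before spline fitting (zero-length chords would break the
parameterisation), empty masks and empty point sets are errors naming the
offending image, and profiles too short for the notch window yield a
warning and no notch calls.

## The synthetic cohort generator

Real ROP images cannot ship with a package; the generator exists so the
*entire* pipeline — rendering, ordering, smoothing, profiling, statistics —
can be validated against known ground truth under realistic population
structure. `cohort_spec()` fixes the study conditions:

* **Zone-conditional minima.** Minimum NERV is drawn per zone from
  `ZONE_PRESETS` (zone I: 276.5 ± 43.2 px; zone II: 360.8 ± 44.5 px;
  TERV analogously 345.0 ± 53.4 / 452.6 ± 52.5). These are published
  cohort parameters and are not free knobs.
* **Pairing.** By default TERV = NERV + d with d ~ Normal(92.2, 34.9) px
  (the published paired difference); alternatively both sides draw
  independently from their zone marginals. One simple generator cannot
  match the zone marginals *and* the paired difference simultaneously, so
  the mode is chosen per experiment: marginal recovery and zone
  discrimination use `independent-by-zone`, asymmetry uses
  `paired-difference`.
* **Arcs.** Each side's junction is a radial function r(θ) spanning 120°
  facing away from the disc (canvas 1600×1200 px, disc near centre, fovea
  240 px temporal to the disc): a base radius plus one low-order cosine
  modulation with amplitude 2–10% of the base, vertically shifted so the
  arc's true minimum equals the drawn value exactly. Notches are
  superimposed Gaussian dips (σ = 4–6° of angle, depth 30–60 px; deep
  temporal notches reach 25–40 px *below* the nasal minimum). Notch
  prevalence defaults to the published per-image frequency (229/1832);
  conditional on a temporal notch, a 0.25 probability of being "deep"
  reproduces the observed ~1.7% rate of inverted asymmetry.
* **Clicks.** A rendered annotation places `n_points = 40` clicks at even
  angular spacing (a careful grader spaces clicks to preserve curvature),
  adds isotropic Gaussian click jitter of 2 px, and shuffles the order.
  Click density and jitter are not published anywhere; these defaults are
  assumptions, exposed as fields of the cohort specification object.
* **VSS.** The AI-derived vascular severity score is simulated as
  `clip(6.0 + 1.2·stage − 0.012·(min NERV) + N(0, 0.8), 1, 9)`. Only the
  ordinal trends are published (VSS rises with stage and with more
  posterior vascularization); the coefficients are chosen to reproduce
  those trends with realistic overlap between stages, not to match any
  printed regression. Stage frequencies follow the published eye-level mix
  (27.6 / 48.8 / 23.6%); the zone mix (30/70) is a plausible
  referral-population choice, as zone counts are not published.
* **Grader duplication.** `duplicate_with_grader_noise` models a second
  grader as a per-image radial placement offset δ ~ Normal(0, σₑ) applied
  to the clicked radii (plus optional independent re-click jitter).
  Per-click isotropic noise alone cannot calibrate reproducibility: the
  minimum of a noisy profile attenuates and biases per-click noise, so the
  measured-minimum error would not equal the nominal σₑ. A per-image
  offset shifts the whole radial profile — and hence the measured minimum —
  by exactly δ, so the closed-form calibration
  σₑ = σ_b·√((1−ICC)/ICC) (`repro_noise_sd`) holds end-to-end. It is also
  the more realistic error model: graders disagree mainly on where the
  junction *is*, coherently across an image, not click-by-click. The
  reproducibility preset uses σ_b = 62 px (consistent with the
  zone-conditional spread, √(43.2² + 44.5²) ≈ 62) and targets ICC 0.985.
* **The asymmetry fixture.** `build_asymmetry_fixture` deterministically
  constructs 476 eyes: 468 with a positive-truncated Normal(92.2, 34.9)
  temporal excess and 8 with a deep temporal notch inverting the
  asymmetry. Its nasal marginal uses Normal(337.75, 52.15) px (the
  published cohort NERV mean; the SD as printed is an evident typo and the
  plausible value is used — it calibrates nothing downstream). Fixture
  annotations are rendered without click jitter so the pipeline's
  classification of every eye is fixed by construction.

### What the generator does and does not emulate

It emulates the *population structure* of the published cohort —
zone-conditional ERV distributions, paired nasal–temporal asymmetry, notch
geometry, stage/VSS covariation, grader disagreement — on idealized smooth
arcs. It does not emulate photographic appearance, vessel trees, plus
disease tortuosity, segmentation ambiguity at faint stage lines, or
optic-disc detection failures. Passing the recovery experiments therefore
shows the measurement pipeline is faithful *given* clicked points and a
disc centre; it says nothing about how hard those inputs are to obtain
from real RetCam images.

### Known bias of the measured minimum

The minimum of a noisy profile is biased low: with 2 px isotropic click
jitter on 40 clicks, the measured minimum sits ≈ 2–3 px below the latent
minimum (the expected minimum of several near-trough noise draws, plus a
small interpolation-overshoot term). This is intrinsic to minimum
statistics, affects real graded images equally, and is why the recovery
experiments compare cohort means at a ±3 px band rather than expecting
unbiasedness. Noise-free renders recover latent minima to well under
0.1 px, isolating the effect to the click noise itself.

## The statistics layer

* `auroc_mann_whitney` — AUROC by pair counting (ties half-weighted),
  oriented so lower ERV predicts zone I; identical to U/(n₀n₁).
* `mann_whitney_test` / `wilcoxon_signed_rank` — two-sided rank tests
  (zone comparisons; paired nasal–temporal comparison). Exact null
  distributions for n ≤ 25 without ties, otherwise the normal
  approximation with tie correction; zero differences are dropped.
* `icc_2_1` — two-way random-effects, single-rater, absolute-agreement
  ICC from the ANOVA mean squares, with the standard F-based confidence
  interval. Implemented directly (and validated against a hand-worked
  ANOVA and the variance-component closed form) since the decomposition
  is part of the surface under test.
* `kruskal_wallis_by_bin` — VSS compared across stages 1/2/3 within
  half-open 75 px bins of minimum NERV/TERV anchored at 0. Bins with
  fewer than 5 eyes in any stage are skipped and flagged — a minimum-count
  rule that prevents degenerate tests. Holm adjustment is applied jointly
  across each side's emitted bins; the published analysis does not state
  its adjustment family, and per-side is the conservative explicit choice.
* `holm_adjust`, `pearson_r` — step-down Holm (delegating to the standard
  routine, verified against hand-applied step-down values) and Pearson
  correlation with its t-based test.
* α = 0.05, two-sided, throughout.

## Validation experiments

The `experiment_*` functions re-run the study's headline analyses on
synthetic cohorts and are what `scripts/acceptance.R` executes:

| experiment | conditions | expected outcome |
|---|---|---|
| `experiment_zone_auroc` | 50 000 latent minima per zone | AUROC ≈ Φ(84.3/62.0) ≈ 0.91 |
| `experiment_recovery` | 2 000 eyes per zone preset, full pipeline | cohort mean within ±3 px of preset |
| `experiment_paired_difference` | 2 000 paired eyes | mean min TERV − min NERV ≈ 92.2 px |
| `experiment_reproducibility` | 729 duplicated images | ICC(2,1) ≈ 0.985 |
| `experiment_asymmetry_fixture` | the 476-eye fixture | 468/476 = 98.3% with NERV < TERV |

Problem sizes (2 000-eye cohorts, 50 000 latent draws, 729 image pairs)
are chosen so sampling error is comfortably inside each comparison band
while a full validation run stays in the minutes range on one core.
Recovery cohorts are generated notch-free: the zone presets describe the
marginal distribution of the minimum, which deep notches deliberately
violate; notch behaviour is validated by the fixture instead.

## Limitations

* Zone III and anterior zone II geometry are out of scope (such images are
  excluded upstream by the visible-disc criterion).
* The meridian angle requires a fovea coordinate; it is reported as NA
  otherwise.
* Greedy ordering can in principle mis-order pathological click patterns
  (self-crossing ridges, extreme clustering); such patterns do not arise
  from the generator and would need manual review on real data.
* The VSS model is a device for producing realistic ordinal structure, not
  a calibrated severity model; coefficient-level conclusions about VSS
  should not be drawn from synthetic cohorts.
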