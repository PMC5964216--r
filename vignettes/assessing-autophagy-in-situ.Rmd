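---
title: "Assessing autophagy in situ: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing autophagy in situ: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctaflux)
```

## The measurement model

Autophagy in fixed tissue is assessed from three families of per-neuron
endpoints: diffuse **expression** of an autophagosome marker (LC3) and a
cargo adaptor (OPTN), counts of their punctate forms (**puncta** —
bright circular dots whose diameters fall in the 0.5–2.0 µm range typical
of autophagosomes), and the **percent of puncta colocalized** across the
two channels, computed separately per channel as
$100\,n_{\text{matched}}/n_{\text{OPTN}}$ and
$100\,n_{\text{matched}}/n_{\text{LC3}}$. Because the pathway moves
material from adaptor-decorated cargo through autophagosomes into
lysosomes, different failure points leave different *direction patterns*
across these seven endpoints, and a decision table over
$\{\uparrow, \downarrow, \text{no change}\}$ can attribute an observed
pattern to candidate dysfunction modes.

The pipeline realizes this chain as pure functions over images:
segmentation → detection → colocalization → per-cell quantification →
nonparametric group statistics → template classification. Every stage is
deterministic given its inputs and the run seed.

## The synthetic-field generator

No suitable raw image data are publicly deposited for this assay, so the
package ships a simulator that plays the role of the microscope and the
tissue, with exact ground truth:

* **Geometry.** Somata are non-overlapping disks (default radius 12 µm) on
  a grid; non-overlap keeps ROI assignment unambiguous and testable.
  Puncta are isotropic Gaussian spots whose full width at half maximum
  (FWHM) equals their stated diameter; diameters follow a scaled Beta law
  on [0.5, 2.0] µm (shape 2.5, 3.5 — mode near 1.1 µm).
* **Hard-core placement.** Punctum centres within a cell keep at least the
  sum of their radii apart. Autophagosomes are solid vesicles and cannot
  interpenetrate; without this constraint, independent uniform placement
  produces sub-resolution pairs (separation below twice the spot width)
  that *no* intensity-based detector can split, which misrepresents the
  counting problem the assay actually poses. A side effect is that
  chance cross-channel colocalization is strongly suppressed, so measured
  percent-colocalized tracks the simulated fraction closely.
* **Optics and noise.** A Gaussian point-spread function (default
  σ = 0.1 µm) blurs soma edges and puncta; for Gaussian spots the blur is
  folded analytically (variances add), and soma edges use the radial
  error-function profile that is the large-radius limit of a blurred disk.
  Poisson-scaled shot noise, additive Gaussian read noise, and integer
  quantization to 12 bits follow. Pixel size defaults to 0.11 µm so the
  smallest admissible punctum spans ≈ 4.5 pixels.
* **Cohorts.** A cohort design fixes ordered stage labels with the control
  first, per-cell baseline rates (default 30 adaptor and 20 autophagosome
  puncta per cell, 40% of adaptor puncta colocalized — giving control
  percent-colocalized near 40% on the adaptor side and 60% on the LC3
  side, the order observed in brainstem neurons), punctum amplitudes
  (log-normal around 150 intensity units, "overtly identifiable" against
  the ~120-unit cytoplasm), per-cell log-normal expression variability
  (CV 0.15), and per-stage multiplicative effects on expression, rates and
  colocalized fraction. Counts are Poisson; colocalized puncta are a
  binomial thinning of adaptor puncta rendered in both channels, and
  autophagosome-only puncta are added so the total LC3 rate meets its
  target.
* **Reproducibility.** Each field derives its own RNG stream from the
  design seed by a fixed affine rule recorded in field provenance;
  identical designs and seeds reproduce images bit for bit.

What the simulator does **not** emulate: 3-D structure, spectral
bleed-through, uneven illumination, neurite morphology, touching cells, or
autofluorescence. Passing tests therefore demonstrate correctness of the
measurement chain under a controlled, favourable model of the imaging
physics — not performance on real tissue, where segmentation and background
estimation face harder conditions.

## The punctum detector

Detection is multi-scale Laplacian-of-Gaussian (LoG) filtering with
scale-normalized responses computed in the frequency domain, after
subtracting a median-filtered local background (window 3 × the maximum
diameter, evaluated on a 4× block-mean downsampled copy — the background
varies on the soma scale, far coarser than the downsampling).

Design choices that matter:

* **FWHM scale convention.** Scales map to diameters via
  σ = d / (2√(2 ln 2)). The measurable "diameter" of a diffraction-limited
  punctum is its FWHM, and the scale-normalized LoG response of a Gaussian
  spot peaks exactly at the spot's σ; the solid-disk convention
  (σ = d/(2√2)) would systematically inflate estimates by ~20% and
  misplace the 0.5–2.0 µm gate.
* **Closed-form diameter refinement.** For an ideal Gaussian spot the
  response at scale σ² = x is ∝ x·x₀/(x + x₀)², x₀ the spot's σ².
  Inverting the ratio of the two strongest scale responses recovers x₀
  exactly in the noise-free case, so the diameter gate separates 2.0 from
  2.1 µm spots even on a four-scale grid, and sizes outside the window are
  rejected without guard scales. Candidates whose ratio admits no
  positive solution carry no coherent blob-scale signature and are
  dropped. The gate allows 2% slack for grid discretization and noise.
* **Shape gates.** Two complementary roundness tests reject soma-edge
  ridges and other non-blob structure: the curvature isotropy of the
  response surface at the peak (√(λ_min/λ_max) of the finite-difference
  Hessian ≥ 0.55), and the minor/major axis ratio (≥ 0.7) of the response
  lobe's support, flooded at 65% of the peak within the peak's Voronoi
  cell among same-scale candidates (so neighbouring lobes do not merge)
  and rejected outright if it reaches the analysis window border. Moment
  ratios are used rather than perimeter-based circularity because
  perimeter estimates on few-pixel digital supports are unstable — an
  ideal digital disk scores ≈ 0.6 with edge-count perimeters.
* **Overlap resolution.** Accepted detections are chosen greedily by
  response further normalized by scale, so two resolved fine-scale peaks
  outrank the single merged coarse response of a close pair; candidates
  within 0.3 of the smaller diameter of an accepted one are duplicates,
  and moderate overlaps (up to half the larger diameter) are resolved by a
  valley test — two real spots show a dip below 85% of the lower peak
  between their centres, cross-scale duplicates of one spot do not. Ties
  break by (row, column), keeping detection deterministic.
* **Relative threshold.** A candidate must exceed 20% of the
  background-subtracted dynamic range above local background, making the
  detector invariant to global intensity rescaling; a constant image has
  zero dynamic range and yields no detections.

Sub-pixel positions come from the response-weighted centroid of the
support; localization error on isolated spots is a small fraction of a
pixel, and the package's validation matches detections to ground truth at
0.25 µm.

## Colocalization

Object-based, not correlation-based: puncta are matched one-to-one across
channels, greedily by ascending centroid distance with a 0.5 µm gate (half
the minimum punctum diameter), ties broken by punctum ids. One-to-one
matching reflects the biology — a colocalized punctum is one physical
adaptor-on-autophagosome site. Cells with a zero denominator report an
undefined percentage that is *excluded* from group means (zero-filling
would bias group averages downward).

## Group statistics

Per endpoint and region the battery computes, on per-cell values:

* the D'Agostino–Pearson omnibus K² (skewness z by the Johnson-SU
  transformation, kurtosis z by the Anscombe–Glynn transformation,
  K² ~ χ²₂) as the normality screen — samples below n = 8 or with zero
  variance are flagged not applicable; the pipeline proceeds
  nonparametrically regardless, which the screen's rejections justify on
  these endpoints;
* the Kruskal–Wallis H with tie correction (χ², k − 1 df);
* only when the omnibus is significant at α = 0.05, Dunn's z on pooled
  ranks with tie correction for each treated stage against the control,
  two-sided p multiplied by the number of vs-control comparisons (k − 1,
  capped at 1). The vs-control family is used rather than all pairs
  because only vs-control contrasts feed the classification.
* A stage is called `up`/`down` only when its adjusted p is below α, with
  the direction taken from group means (the reporting scale of the assay);
  a non-significant omnibus forces `no_change` everywhere.

Cells are the unit of analysis. This matches how such assays are reported
(hundreds of neurons per region) but ignores animal-level clustering; the
statistics are calibrated for the simulated design, where cells are
genuinely independent, and would be anti-conservative under strong
per-animal effects.

## The dysfunction decision table

Six categories are encoded as direction templates over three evidence
blocks (expression, puncta counts, percent colocalized): autophagy induced
with flux unimpaired, impaired induction, impaired OPTN–LC3 interaction,
failed autophagosome–lysosome fusion, OPTN failure or exhaustion, and
autophagosome failure or exhaustion. The templates ship as a reviewable
CSV (`inst/extdata/dysfunction_templates.csv`), one record per table cell,
with `|`-separated admissible calls and `any` where the underlying theory
makes no prediction.

Scoring: a block is **full** when every endpoint call lies in its expected
set, **inconsistent** when a call is the direction opposite to every
member of a single-direction expectation, **partial** otherwise. A
category is **matched** when no block is inconsistent and at least one
*evidentiary* block — one whose template expects an actual direction
somewhere — is full. The evidentiary qualifier exists because the
induced-flux category's percent-colocalized block expects "no change"
everywhere; without it, a completely flat pattern would "match" that
category on trivially satisfied non-evidence. All consistent categories
are reported rather than a forced single winner: the table genuinely
cannot separate some modes (impaired interaction and autophagosome
exhaustion share an identical expression row), and the honest output is
the set.

Two documented tensions in the underlying table: the impaired-induction
puncta row reads "OPTN ↓ or no change" in the primary table but "OPTN
increased or no change" in its prose restatement — the templates
transcribe the primary table and do not harmonize the two. And the
induced-flux row is arithmetically over-constrained in any static data
set: if LC3 puncta rise while colocalized counts are unchanged, the
percent of LC3 puncta colocalized must fall (it is the ratio of the two),
so that row's percent block cannot be fully satisfied alongside its
puncta block; the category is still correctly *matched* through its
expression and puncta evidence.

## Scenario designs and validation conditions

`scenario_from_category()` maps each category to multiplicative effects on
the generator baselines (e.g. failed fusion: ×1.5 expression on both
markers, ×1.7 both puncta rates, ×1.5 colocalized fraction; impaired
induction: ×0.5 LC3 rate with the colocalized fraction halved in step so
the LC3-side percentage stays flat, as that category's template demands).
These are large effects by design — they validate that the pipeline's
calls land where the templates say they should, not that subtle effects
are detectable.

End-to-end validation runs at a deliberately compact problem size
(`scenario_conditions()`): 0.165 µm pixels, 25 somata of 4.5 µm radius per
51 × 51 µm field, 9/6 puncta per cell, 100 cells per stage, three
detection scales. One full scenario — simulate, segment, detect, match,
test, classify — takes a few seconds, so the six-category, 20-seed
recovery study completes in minutes. The headline studies (detection F1,
colocalized-fraction recovery) run at the default 12 µm/30-puncta scale.

## Numerical and degenerate-input conventions

* Frequency-domain Gaussian and LoG kernels use the exact continuous
  transfer functions; circular wraparound is irrelevant because scene
  content keeps a margin from the field border.
* Blank or constant images segment to zero ROIs and detect zero puncta —
  neither is an error.
* All-identical samples give H = 0, p = 1; empty control groups and
  missing pattern slots are errors.
* CSV outputs round to 10 significant digits so that re-runs are
  byte-identical; manifests record seeds, configuration, row counts and
  MD5 digests of every table.

## Known limitations

* 2-D single-plane only; real confocal stacks would require volumetric
  detection and a different colocalization gate.
* The detector's diameter estimate degrades for spots near the pixel
  scale (σ below ~1.5 px); the default pixel sizes keep the admissible
  range safely above this.
* Merged pairs closer than roughly twice the blurred spot width remain
  undetectable in principle; the generator's hard-core placement keeps
  their frequency low rather than zero.
* Animal-level clustering is not modelled (see above).
* The decision table attributes patterns, it does not infer mechanism:
  several categories can and do co-match.
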