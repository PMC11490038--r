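---
title: "Methods: viability quantification and substantivity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viability quantification and substantivity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvquant)
```

## The measurement problem

LIVE/DEAD (SYTO 9 + propidium iodide) double staining separates intact from
membrane-compromised bacteria by fluorescence colour: SYTO 9 enters all
cells and emits green, PI enters only damaged cells and emits red. Confocal
laser scanning microscopy turns a stained saliva smear or an in situ grown
plaque biofilm into a registered two-channel z-stack, optically sectioned at
0.71 µm from the biofilm surface down to the substrate. The quantity of
interest is the bacterial viability percentage (BV) of each optical section,

$$\mathrm{BV} = 100 \cdot
  \frac{\#\,\text{viable pixels}}{\#\,\text{viable} + \#\,\text{non-viable pixels}},$$

aggregated per field, per sample, and — for biofilm — per depth layer, and
finally compared across the timepoints of a two-product crossover trial to
measure substantivity (how long a single antiseptic application keeps
viability suppressed).

## Pixel classification

Working on the 0–255 intensity scale, a pixel is **viable** when green > 100
and red < 100, **non-viable** whenever red > 100 (this includes the visually
orange pixels high in both channels: PI entry already marks the membrane as
compromised, whatever the SYTO 9 level reads), and **background** otherwise.

Three numerical choices deserve note:

* **Strict inequalities.** The rule is applied exactly as stated, so a pixel
  sitting at precisely 100 in a channel satisfies neither the "high" nor the
  "low" test of that channel. In particular a pixel with green > 100 and red
  exactly 100 is background: it fails both the viable rule (red < 100) and
  the non-viable rule (red > 100). This is a documented consequence of the
  strict bounds, not an oversight; with 8-bit data the measure of affected
  pixels is negligible.
* **Red precedence.** red > 100 forces non-viable even when green ≤ 100,
  because PI positivity alone defines the dead population.
* **Depth rescaling.** Data deeper than 8 bits are linearly mapped so the
  full bit range lands on 0–255 before thresholding, keeping the thresholds
  meaningful across acquisition depths.

Both thresholds are configurable (`bv_config(green_thr =, red_thr =)`) but
default to 100/100; the package deliberately does *not* offer adaptive
(e.g. Otsu) thresholding, as fixed expert-set thresholds are what makes BV
comparable across samples and timepoints.

## Epithelial-nucleus exclusion

Shed epithelial cells carry large, PI-bright nuclei that would otherwise be
counted as non-viable bacteria. The filter works on connected components of
the non-viable (red-dominant) pixel population of each section, built with
8-connectivity by default (compact nuclei are insensitive to the choice;
8-connectivity avoids fragmenting diagonal boundaries, and 4-connectivity is
available via configuration). A component is a nucleus when it satisfies all
three of:

| criterion | bound | default |
|---|---|---|
| area | strictly greater | 200 px |
| solidity (area / convex-hull area) | strictly greater | 0.70 |
| mean red intensity | at least | 180 |

The three tests are a conjunction: they describe joint properties of one
object class, and any single test alone would misfire (large sprawling
aggregates fail solidity, small bright debris fails area, dim compact
clumps fail intensity). "Bright" is operationalised solely by the mean-
intensity bound of 180 rather than as an extra qualitative test.

**Solidity convention.** The convex hull is taken over the *corners* of the
member pixels, and the hull area is the number of pixels whose centre falls
inside or on that polygon. Under this convention any solid rectangle — and a
single pixel — has solidity exactly 1, and a 2×3 block missing one corner
has solidity 5/6. (A hull over pixel *centres* would degenerate for thin
shapes and call the notched block perfectly solid.)

Flagged components are relabelled background, so exclusion can only move
pixels out of the non-viable count: viable counts are untouched and
per-section BV can only rise. Both pre- and post-exclusion BV are retained
in every report, and exclusion runs *before* the area gate and all
aggregation, so gating decisions see the cleaned sections.

Components are extracted per section, not on a projection: nuclei are
optically thin relative to the stack, and per-section analysis keeps the
exclusion consistent with the per-section BV bookkeeping. Cross-section
(3-D) merging of nucleus fragments is intentionally out of scope.

## Gating, thickness and layers

A section enters field means only when its bacterial aggregate area
(viable + non-viable pixels × pixel area) reaches **250 µm²** — about 4,750
pixels at the default lateral pixel size of 0.2294 µm/px, which is exactly
the pixel size at which those two printed constants agree and is overridable
for other optics. Sections with no bacterial pixels have undefined BV and
are never included; a field whose sections all fail the gate is excluded,
and a sample whose fields are all excluded is flagged missing rather than
silently dropped.

The **maximum field thickness (MFT)** is the distance between the substrate
and the peaks of the highest bacterial clusters: scanning surface-to-base,
the anchor is the shallowest section whose largest bacterial connected
component reaches the cluster gate `min_aggregate_px`, and
`MFT = (n_sections − anchor + 1) · z_step`. The cluster gate defaults to
the pixel equivalent of the 250 µm² area gate — the only cluster-size
constant the analysis defines — but is configuration-exposed, and analyses
of synthetic stacks routinely scale it down (see below).

The MFT span splits at MFT/2 into an **upper** (surface-side) and a
**lower** (substrate-side) layer. With an odd number of in-span sections the
middle section joins the upper layer; the two layers always partition the
span. Layer BV defaults to the mean over included sections
(`layer_bv = "slice_mean"`); a pixel-pooled variant (one ratio from summed
counts) is available since the aggregation convention is not dictated by
the BV definition itself.

An alternative **harmonised** layer mode addresses depth-comparability
across a trial: the common layer span is the minimum, over gel × timepoint
cells, of the median per-field MFT, and that single span is applied to
every field (sections deeper than the common span stay unassigned). The
default remains the per-field MFT/2 split; both modes are available because
the trial-level harmonisation rule admits more than one reading, and
keeping both labelled is safer than silently choosing.

Saliva samples are quantified on the **maximum-intensity projection** of the
stack — classification, exclusion and BV on a single projected section, with
no thickness or layers. Max projection is the standard overall-view operator
for confocal stacks and commutes naturally with threshold classification
(a pixel is bright in the projection iff it is bright in some section);
this operator choice is the package's own.

## Trial statistics

Descriptives are mean ± sample SD (n − 1) and median with IQR
(Q3 − Q1, linear interpolation between order statistics — quantile type 7,
recorded in output metadata). The Shapiro–Wilk screen is reported for
transparency only: the pipeline is nonparametric regardless of its outcome,
matching how such trials are analysed in practice; constant input returns a
degenerate flag rather than an error.

Comparisons use two-sided Wilcoxon tests: signed-rank (paired) within a gel
across timepoints, rank-sum (independent) between gels at a timepoint. The
intra-gel family comprises baseline vs each of the five post-application
times plus the five-minute sample vs each later time (nine tests per gel);
the inter-gel family is one test per timepoint (six). Significance levels
are Bonferroni-adjusted: 0.05/5 = 0.01 intra-gel and 0.05/6 = 0.00833…,
displayed truncated to 0.008, inter-gel. The family sizes (5 and 6) are the
ones that reproduce those two printed levels and are configuration-exposed,
since nine tests are tabulated per gel while the threshold corresponds to a
family of five — the de facto family was evidently the baseline contrasts.
An inter-gel *paired* mode exists behind a flag (the crossover design would
permit it) but is off by default, following the independent-samples
convention of the reports this package mirrors.

**Exact vs approximate.** The exact null distribution is used when the
effective sample size is at most 29 and the data carry no ties (and, for
the paired test, no zero differences); otherwise the normal approximation
with continuity correction and mid-ranked ties applies, and the method used
is recorded in the result. Zero differences are dropped (the standard
signed-rank convention); a paired comparison whose differences are all zero
is flagged degenerate with p = 1. The smallest attainable two-sided exact
signed-rank p for n pairs is 2^(1−n) — for n = 29, 2/2²⁹ ≈ 3.7253·10⁻⁹ —
which is why substantivity tables built on 29 subjects bottom out at
p-values of that magnitude. P-values are computed at full precision and
displayed at 4 significant figures (scientific below 10⁻⁴).

## The synthetic generators

`generate_stack()` paints what the classifier is designed to see:

* **bacterial aggregates** as flat-core disks of radius 1–4 px (peak
  intensity 160–240) with a dim sub-threshold halo ring at intensity 50,
  assigned to the viable (green) or non-viable (red) channel by a
  largest-first greedy split that holds the realised viable area fraction
  within half a blob area of the target;
* **epithelial nuclei** as solid bright-red ellipses (semi-axes 9–14 px,
  intensity 190–235) that satisfy all three nucleus criteria by
  construction, while blob areas (≤ 49 px) keep bacteria below the area
  criterion by construction;
* **background noise** uniform on [0, 40] in both channels.

Because every painted intensity is at least 60 units away from the 100
thresholds and the noise ceiling is 40, no pixel can cross a threshold
ambiguously: the painted core masks are *exactly* the classified masks, and
ground truth (per-section viable fraction, nucleus masks, thickness) is
known without approximation. Blobs are placed without overlap (rejection
sampling with a one-pixel margin), so components never merge; a spec that
cannot be placed raises a generation error rather than degrading silently.
Thickness defaults to a uniform draw from 11–19 µm — the realistic median
range for 48-hour in situ biofilm — rounded to whole 0.71 µm sections, with
noise-only sections above the surface.

This generator intentionally does **not** emulate point-spread blur,
photobleaching, spectral bleed-through, intensity gradients with depth, or
touching/overlapping objects. Passing recovery tests therefore demonstrate
that the *quantification logic* is correct (classification, morphology,
gating, aggregation, bookkeeping), not that the fixed thresholds are robust
to real optical degradation — that robustness was established upstream by
expert calibration of the thresholds, which this package takes as given.
One practical consequence of the stylised blobs: no single synthetic
cluster reaches the default ≈ 4,750 px MFT cluster gate, so synthetic
thickness analyses scale `min_aggregate_px` down (tests use 40–100 px);
with real 2048 × 2048 fields the default gate is the intended one.

`generate_trial()` draws per-subject BV trajectories from
`mean + sd · (√ρ·u + √(1−ρ)·e)` with a shared standard-normal subject
effect `u` (within-subject correlation ρ, default 0.5 — a middle-ground
value, as crossover reports rarely print correlations) and clamps to
[0, 100]. Normal marginals are a simplification — real BV data are skewed
and non-normal, which is precisely why the pipeline is nonparametric — but
means and SDs are all such reports print, and clamping reproduces the
boundary pile-up near 0 that post-application biofilm data show. Built-in
per-(gel, timepoint) means and SDs for both niches and all biofilm layers
are available through `reference_summaries()`.

On the simulated-trial acceptance check: with 29 subjects the
baseline-vs-post washout is detected at the 0.01 level in essentially every
replicate. The *joint* pattern that additionally requires all six inter-gel
tests non-significant at 0.008 reproduces in roughly 80–90% of replicates,
not ≥ 95%: a few printed between-gel cells differ by ~0.3–0.5 pooled SDs
(e.g. saliva at 1 h), so the independent rank-sum test rejects with
~10–15% probability in those cells, and the product over six cells caps
the joint rate. The corresponding assertion is kept at its stated bound and
fails honestly rather than being loosened; it documents a real property of
simulating from those summary statistics, not an implementation defect.

## Degenerate inputs and tie-breaks

* Empty sections: BV undefined (`NA`), never included, never an error.
* MFT = 0 (no qualifying cluster): both layers empty, layer BVs `NA`.
* Odd in-span section counts: middle section to the upper layer.
* All paired differences zero: degenerate result, p = 1.
* Constant vectors: SD = IQR = 0; Shapiro–Wilk degenerate flag.
* Unreadable stacks in a pipeline run: recorded per-field failure, run
  continues, summary lists failures, exit stays clean.
* Pixels exactly at a threshold: background (strict inequalities).

## Problem sizes used by the test suite

Synthetic fields are 256 × 256 px (or smaller) with ~250 aggregates per
section and thickness drawn from the realistic 11–19 µm band; trial
simulations use 29 subjects with 200 replicates for pattern checks and 400
for null calibration. These sizes are chosen so that the full suite
exercises every stage at full fidelity while remaining comfortable to run
on a laptop; all constants scale to full-size 2048 × 2048 acquisitions
through the configuration without code changes.

## Known limitations

* Fixed global thresholds; no per-field re-estimation by design.
* Per-section (2-D) nucleus detection; a nucleus spanning many sections is
  excluded section-wise, and touching nuclei are not watershed-split.
* The MFT cluster-gate default reuses the slice-gate constant; other
  operationalisations of "peaks of the highest cell clusters" are possible
  and the gate is exposed for that reason.
* No crossover-specific modelling (period or carryover effects, mixed
  models); the statistics reproduce the established nonparametric recipe.
* No optical realism in the stack generator (see above).
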