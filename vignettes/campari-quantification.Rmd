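---
title: "Quantifying CaMPARI photoconversion snapshots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CaMPARI photoconversion snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campariq)
```

## The measurement problem

CaMPARI is a calcium-modulated photoactivatable ratiometric integrator: a
fluorescent protein that irreversibly converts from green to red under
400 nm illumination, but only in cells with elevated intracellular calcium.
Shining photoconversion (PC) light over a behaving animal therefore imprints
a snapshot of neuronal activity that can be read out later with a two-photon
microscope, separately from the recording itself. The per-cell readout is
the red-to-green fluorescence ratio (RGR): cells that were more active
during illumination carry more converted (red) protein relative to their
remaining green pool.

Turning two-channel image stacks into comparable RGR values requires a chain
of corrections and summaries, each of which this package implements as a
tested function:

1. **Dark current** — each PMT channel has an offset measured from
   laser-off frames (`estimate_dark_current()`).
2. **Spectral contamination** — green emission leaks into the red channel.
   Before PC no converted protein exists, so regressing dark-corrected red
   on dark-corrected green across pre-PC cells yields the leak fraction
   $\rho$ as the slope (`estimate_contamination_ratio()`).
3. **Autofluorescence offset** — each cranial window sits at its own angle
   to the optical axis and contributes a weak red baseline $\beta$,
   estimated per hemisphere as the intercept of the same regression
   (`estimate_autofluorescence_intercept()`, or jointly with a shared slope
   via `estimate_corrections()`).
4. **RGR** — after `apply_corrections()` (order fixed: darks, then $\beta$,
   then $\rho \cdot g_{corr}$ off the red channel), the standard readout is
   $RGR = r_{corr}/g_{corr}$ per cell (`compute_rgr()`). A paired variant
   $(r_{post}-r_{pre})/g_{post}$ serves preparations with pre-existing red
   puncta; subtracting the same cell's pre-PC red removes any static red
   offset, so no separate $\beta$ is applied there.

Population comparisons use region summaries (median, quartiles, the 5–95
percentile range as an activity-range metric; `summarize_region()`) and the
sensitivity index

$$ d' = \frac{\bar{x}_A - \bar{x}_B}{\sqrt{0.5\,(s^2_A + s^2_B)}} $$

between two RGR distributions (`dprime()`). Sample variances ($n-1$) are
the default; the choice is switchable (`var_type = "population"`) because
either convention is defensible for empirical distributions of hundreds of
cells, and the difference is negligible at those sizes.

## Synthetic data as the validation substrate

Animal-derived stacks are not required to validate the arithmetic of this
chain. `make_scene()` places non-overlapping spherical somata with known
region, hemisphere, latent activity $a \in [0,1]$ and baseline green
brightness; `render_scene()` renders them into two-channel volumetric
stacks under a phenomenological PC model plus the optical nuisances the
corrections exist to remove:

* conversion fraction $c(dose, a) = a \cdot c_{max}(1 - e^{-dose/\tau})$
  (zero at zero dose, saturating, monotone in activity),
* dose-linear green bleaching, calibrated so the dose-dependent green
  factor is 60% at 300 dose units,
* per-voxel means: green $= b(1-c)\,gf \cdot att + dark_g$, red
  $= b\,c\,rbr \cdot att + \rho \cdot green_{sig} + \beta + dark_r$,
* Gaussian noise with variance $shot \cdot signal + read^2$ (the standard
  PMT shot + read model).

The model is a rendering device, not a claim about CaMPARI photophysics;
its defaults are pinned only to the printed anchors (green retention 60% at
dose 300; red gain increasing and concave). Because every cell's true
converted red, true green and true RGR are stored, the pipeline admits
exact oracles: in the noiseless limit, estimate-then-apply corrections
recover each cell's true signals to machine precision, and recovered RGR
equals the closed-form `true_rgr()` exactly. Under default noise, recovered
RGR preserves activity ranks (Spearman ≥ 0.95 is asserted in the tests).

What the generator deliberately does **not** emulate: optical PSFs,
intracellular texture, motion artifacts, segmentation ambiguity from
overlapping somata, slow drift, or biological variation in conversion
efficiency per cell. Passing tests therefore certify the quantification
arithmetic, not robustness to those real-data effects.

Dose bookkeeping: one dose unit is 1 mW/mm² · 1 s = 1 mJ/mm². Published
protocol figures quote the same numbers as "J/mm²", which is inconsistent
by ×10³ with the power/aperture/time arithmetic they accompany (200 mW over
~33 mm² for 1 s is 6 mJ/mm²); `light_dose()` follows the numeric scale of
those printed figures and reports mJ/mm², documenting rather than resolving
the unit discrepancy.

## Depth sampling and segmentation

Volumetric readouts are depth-sampled by **slab averaging**
(`slab_average()`): average every 3 adjacent z-slices (6 µm at the 3 µm
step), skip the next 2, so consecutive slabs contain mostly disjoint cells.
Trailing incomplete groups are dropped rather than averaged — padding would
silently change the noise level of the last slab. A slab's depth is the
mean depth of its slices; cells inherit their slab's depth for the
depth-flatness comparison (`anova_oneway()` across depth groups).

Cell masks from dedicated tools (CellPose and similar) are first-class
inputs (`read_label_tiff()`, the pipeline's `external` source). The
built-in fallback (`segment_cells()`) is deliberately simple and
deterministic: Gaussian smoothing (σ = 1 px), a global threshold at a
quantile (default 0.5) of the nonzero pixels, 8-connected component
labeling, and an area filter. Numerical details that matter: smoothing
introduces ±1e-14 ripples, so "nonzero" means above `max(img) · 1e-6`; the
threshold comparison is `>=` so a quantile of 0 keeps the dimmest nonzero
pixel; 8-connectivity is obtained by a union-find merge of diagonally
touching 4-connected components. The quantile design assumes a
background-free image, so the pipeline's builtin path first removes the
flat acquisition background (slab median + 5·MAD) — on raw
background-carrying images the quantile would land in the noise floor and
bridge neighboring cells. These defaults were chosen to meet the fallback's
contract (count-level agreement with ground truth ≥ 95% on rendered
scenes); only count-level fidelity is claimed for the fallback.

Pre/post acquisitions are matched by mutual nearest centroid neighbours
under a distance cap (`match_cells_pre_post()`); mutuality, not greedy
assignment, keeps jittered masks ≥ 99% correctly paired in the tests.

## Decay, dose-response, and dynamic comparator

The red signal is not permanent in vivo: converted protein degrades and new
green protein is produced, so RGR decays over days.
`simulate_decay_cohort()` generates per-cell normalized time courses
(day 0 exactly 1 by construction; expectation $2^{-t/t_{1/2}}$ with
default half-life 1.04 d over days 0–15, n = 73 cells) with multiplicative
lognormal noise of CV 0.2 chosen median-unbiased so across-cell medians stay
on the exponential. `fit_decay()` fits $y = A\,2^{-t/t_{1/2}} + C$ by
nonlinear least squares (`minpack.lm::nlsLM`, started from the log-linear
slope); the default fixes $A = 1, C = 0$ because traces are normalized at
day 0, and frees are available because observed week-long losses (~97%)
sit slightly below the pure exponential's prediction (~99%). $R^2$ is
reported against the constant-mean model, and the fitted model's predicted
loss at 7 days exceeds 97%.

`fit_dose_response()` fits plain least-squares polynomials on the printed
dose scale (3rd order for d′, 1st for green, 2nd for red in the original
characterization) and locates the fitted maximum on a dose grid (1 dose
unit spacing by default). The d′-vs-dose optimum near 300 is an emergent
property of real data that the generator is not calibrated to reproduce, so
the fit is validated on constructed curves with known peaks. Whether a
dose-response point pools cells per session or takes per-mouse medians is
left to the caller — both aggregations are one `summarize_region()` call.

For the dynamic comparator (jGCaMP7s), `simulate_grating_traces()` emits
boxcar responses under the drifting-grating protocol (8 directions, 4 s
grating + 8 s gray, 5 repeats at 15 fps; the comparator variant 4 s/4 s at
30 fps), and `integrate_grating_response()` scores each appearance as
$\sum F_{resp}/2 - \sum F_{base}$ with a 2 s baseline window — the response
window is twice the baseline, so a constant trace scores exactly zero. A
first grating with no full baseline window is skipped with a warning.

## Statistics

`compare_groups()` wraps the two-tailed tests used for regional and task
contrasts. The rank-sum statistic is reported as the sum of midranks of the
first group (the convention in which such statistics are quoted; which
group is summed and midrank tie handling are not universal, so the choice
is documented here), with exact small-sample p-values. The two-sample t
defaults to the Student (equal-variance) form with Welch behind a flag —
the source analyses do not state which form they used. `anova_oneway()`
performs the standard one-way decomposition (F = t² for two groups, a
tested identity), and `correlate_behavior()` regresses a behavioral score
on regional median RGR, reporting the F of the model against the constant
model (equal to the squared slope t). No multiple-testing correction is
applied by default, mirroring the source analyses; `p.adjust()` composes
trivially for users who want it.

Degenerate inputs have defined behavior rather than errors where a value is
meaningful: identical constant groups give d′ = 0 (and t = 0, p = 1);
constant groups with unequal means give signed infinite d′ with a warning;
all-equal ANOVA input gives F = 0, p = 1; negative fitted contamination
slopes are clamped to 0 with a flag; cells with non-positive corrected
green are excluded and counted, never clipped.

## The pipeline and reproducibility

`run_pipeline()` chains the six stages (simulate → correct → segment → rgr
→ metrics → stats) from one configuration (`pipeline_config()`, or YAML via
`read_pipeline_config()`), writing TIFF stacks, CSV tables, JSON fits and a
manifest that records every stage's parameters and seed. One global seed is
fanned out to per-stage child seeds by a documented derivation
(`stage_seed()`: `(seed·131 + index·7919) mod (2^31 − 1)`), so a stage can
be re-run in isolation and a full re-run is byte-identical — both are
asserted in the tests.

Problem sizes used throughout the package's own validation were chosen as
comfortable desk-scale stand-ins for the original acquisitions: scenes of
40–120 cells in 128–160 px × 8–12 slice volumes rather than 1024² × ~100;
decay cohorts of 73 cells; 1000-instance d′ oracle sweeps; all group/skip
combinations in {1..4} × {0..3} for the slab oracle.

## Known limitations

* The fallback segmenter under-splits genuinely touching somata; import
  masks from a dedicated tool for crowded fields.
* The PC model is phenomenological; absolute RGR values are comparable
  within a configuration, not across different `pc_model()` settings.
* Depth attenuation defaults to zero (flat superficial-layer readout);
  channel-specific attenuation is available but uncalibrated.
* The paired variant assumes perfect pre/post cell identity; matching
  errors propagate directly into its numerator.
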