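---
title: "Early-vigour phenotyping of field pea from multi-view colour images"
author: "peavigour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-vigour phenotyping of field pea from multi-view colour images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peavigour)
```

## The measurement problem

Early vigour in field pea (*Pisum sativum*) is conventionally scored by
destructive harvest: fresh shoot biomass, leaf area and plant height.
Automated imaging platforms replace the harvest with daily photographs —
one top view and three side views of each potted plant, rotated by 0, 120
and 240 degrees — and with a deliberately colour-coded scene: green plant
tissue, a blue wire support cage, and a white pot and background. Because
the three materials are separable in colour space, plant pixels can be
selected by a simple colour rule, and pixel sums act as non-destructive
surrogates for biomass and architecture. `peavigour` implements the
analysis chain from raw multi-view images to a ranked genotype table, and
pairs it with a synthetic-data generator so every stage can be verified
against known ground truth.

## Digital traits

For each plant-day the four views are segmented
(`segment_plant()`), denoised (`denoise_mask()`) and summarized
(`extract_traits()`):

* `EB` (estimated shoot biomass, kilopixels): the sum of plant pixel
  counts over the three side views *plus* the top view, divided by 1000.
  The sum (rather than a mean of views) is used; downstream statistics
  are scale-consistent either way.
* `TVA` (top-view area, kPix): the top-view plant pixel count / 1000.
* `TVCH` (top-view convex hull, kPix): the area of the filled convex
  hull of the top-view plant object. The hull is taken over the *squares*
  of the plant pixels (all four cell corners), then rasterized back onto
  the grid by counting cells whose centres lie in the closed hull. This
  convention makes the hull a superset of the plant region, so
  compactness is bounded: a plus-sign of five unit pixels, for example,
  has a hull covering its full 3×3 bounding cross and `TVCOM = 5/9`.
* `TVCOM` = `TVA / TVCH` in [0, 1]: canopy compactness; 1 for convex
  canopies.
* `EH` (estimated plant height, pixels): the inclusive row extent
  (`max row − min row + 1`) of the plant object, maximized over the
  three side views.

Segmentation operates in hue–saturation–value space (`rgb2hsv()` hues on
[0, 1]): a pixel is plant tissue when its hue lies in the green window
(default [0.18, 0.45]) with saturation ≥ 0.20 and value ≥ 0.10, and it is
not captured by the blue cage rule (hue in [0.52, 0.80], saturation ≥
0.20). The windows are configuration knobs; the defaults are tuned to the
synthetic palette and are a starting point, not a calibration, for real
camera data. Denoising removes 8-connected components below `min_size`
(default 50 px). No pixel-to-centimetre calibration is applied: digital
and manually measured traits are compared only by correlation and rank.

An image whose denoised mask is empty produces a *flagged* record (the
affected traits are `NA` and the view is named in a `flags` column), not
an exception, so batch runs never abort on a failed acquisition.

## The two-phase growth model

Seedling biomass accumulation shows a lag phase followed by a linear
growth phase. `fit_broken_stick()` fits the continuous "broken-stick"
model
$$y(t) = \begin{cases} Y + s_1\,(t - X), & t \le X\\
                       Y + s_2\,(t - X), & t > X \end{cases}$$
with the two lines constrained to meet at the breakpoint $(X, Y)$. For a
fixed $X$ the model is linear in $(Y, s_1, s_2)$ through the basis
$\{1,\; t - X,\; \max(t - X, 0)\}$, so estimation profiles $X$:

* candidate breakpoints on a dense grid (default 0.01 day) between the
  2nd and $(n-1)$th observed days, which keeps at least two observations
  strictly on each side;
* conditional least squares at each candidate; ties in the profiled SSE
  are broken toward the smallest $X$ (within a small numerical
  tolerance, so an exactly flat profile resolves deterministically);
* a local `optimize()` refinement around the best grid point.

This estimator is deliberately simple and oracle-checkable: the test
suite verifies its SSE against a brute-force scan over 10,000 candidate
breakpoints, and round-trips all 44 packaged reference parameter sets
(noise-free regeneration at days 11–39, refit, recovery of $X$ within
0.05 day and both slopes within 0.5%). Adjusted $R^2$ uses $p = 4$ free
parameters. Perfectly collinear data are not an error: the fit comes
back with `degenerate = TRUE`, both slopes equal to the single-line
slope, $X$ at the first grid point of the flat SSE profile, and a
warning — so batch fitting over many genotypes never aborts.

Fitting is done per genotype on per-day replicate means
(`fit_genotypes()`), matching how genotype-level trajectories are
reported; replicate-level fitting is available by passing the replicate
series directly.

The *linear-phase onset* (`linear_phase_onset()`) is the smallest
integer day strictly greater than the largest fitted breakpoint, i.e.
the first day on which every genotype is in its linear phase; applied to
the packaged panel (latest breakpoint 26.26 DAS) it gives day 27, the
common comparison day used by the ranking stage.

## Vigour statistics

* `rgr()` — relative growth rate
  $(\overline{\ln W_2} - \overline{\ln W_1})/(t_2 - t_1)$: logs per
  replicate first, then averaged.
* `ewue()` — biomass per kilogram of supplied water. Water amounts are
  an input (real platforms log them; the simulator generates them);
  they are never imputed.
* `ndvi()` — the Rouse index $(R_{760} - R_{670})/(R_{760} + R_{670})$
  from red/near-infrared reflectance fractions.
* `detect_outliers()` — Tukey boxplot fences $[Q_1 - 1.5\,\mathrm{IQR},
  Q_3 + 1.5\,\mathrm{IQR}]$ with type-7 (linear interpolation)
  quartiles, applied to replicates within each genotype before means
  are taken.
* `one_way_anova()` — the standard one-way decomposition;
  $\mathrm{s.e.d.} = \sqrt{2\,\mathrm{MSE}/n}$ and
  $\mathrm{LSD} = t_{0.975,\mathrm{df}} \cdot \mathrm{s.e.d.}$; for
  unbalanced groups the harmonic mean group size is used, with a
  warning. A within-group mean square of zero yields $F = \infty$,
  $p = 0$ when the group means differ and `NA` when all values are
  identical.
* `pearson_matrix()` — product-moment correlations with two-sided
  p-values from the $t$ transform on $n - 2$ degrees of freedom and
  stars at 0.05/0.01/0.001. Pairwise-complete handling is recorded in
  the result; correlation p-values are reported unadjusted.
* `rank_genotypes()` — genotype means of the screened traits, per-trait
  ANOVA columns, and ranks descending by measured biomass `mb` when
  present, else by `eb_kpix`; ties break by `eb_kpix`, then genotype
  name. Compactness is averaged per plant *before* the genotype mean
  (the ratio of trait means is close to, but not identical with, the
  mean per-plant ratio). When reflectance records are supplied, the
  NDVI–EB and NDVI–TVA correlations across genotypes are reported.

The greenhouse layout's blocking structure is not modelled (one-way
ANOVA only), and no multiple-testing adjustment is applied by default.

## The synthetic-data generator

`scene_spec()`/`make_scene()` emulate only what the segmentation stage
depends on: the colour composition of the scene. Plant silhouettes are
parametric (a stem with leaf blobs in side views, a blob rosette in the
top view) and are grown or trimmed to an exact per-view pixel count, so
segmentation tests have an exact oracle; the cage occludes the plant
where they overlap (it is physically in front), and the visible plant is
adjusted to the requested count after occlusion. A validator enforces
that the three palette colours differ by more than `2 * noise_sd` in at
least one channel — the condition under which the colour rule is a
correct segmenter. Gaussian per-channel noise is added after all
geometry is drawn, so the ground truth (per-view counts, top-view hull
area, side-view heights) is invariant to the noise level. What the
generator does **not** emulate: realistic pea morphology, overlapping
leaves (a known negative bias of image-based biomass on real plants),
shadows, specular highlights, or soil. Passing tests therefore certify
the *computations*, not the colour thresholds' fitness for any
particular camera.

`simulate_growth()` draws replicates as $m(t)\,(1 + \mathrm{cv}\,
\varepsilon)$ with standard normal $\varepsilon$ — multiplicative noise,
chosen because biomass measurement error scales with plant size; no
residual model is published for the reference panel, so the default
`cv = 0.03` is this package's choice of a realistic replicate spread
(it reproduces the panel's reported fit quality, adjusted $R^2 > 0.99$,
at 8 replicates). Values are truncated at a small positive floor
(`1e-6` kPix) so log-traits stay defined. Three reference parameter
rows have lag lines that extrapolate marginally below zero at 11 DAS
(split-line fits are not positivity-constrained); the simulator
therefore rejects non-positive model values only from the breakpoint
onward and emits floor values in the early lag phase. The day grid
defaults to integer DAS 11–39, the observation window of the reference
experiment.

`simulate_field_ndvi()` links genotype biomass to plot NDVI through an
affine map (default: the biomass range onto NDVI 0.3–0.8, a typical
canopy range) plus Gaussian noise, and emits $(R_{670}, R_{760})$ pairs
with a fixed band sum (default 0.8) whose Rouse index reproduces the
linked NDVI exactly.

Every stochastic operation takes one integer seed and restores the
caller's RNG state (R's default Mersenne-Twister generator); pipeline
sub-seeds are derived from the run seed by fixed offsets.

## Pipeline and configuration

The four stages (`run_simulate()`, `run_extract()`, `run_fit()`,
`run_analyze()`, or the `exec/peavigour` subcommands) communicate only
through files under one output directory: PNG images named
`<plant_id>_<das>_<view>.png`, CSVs with documented columns, a manifest
listing every artifact (relative paths), and per-stage structured logs.
Identical config and seed reproduce CSV outputs byte for byte. The YAML
configuration is validated against a schema: unknown keys and
out-of-range values are rejected with the offending field named.
Defaults mirror the reference experiment scale (44 genotypes, 8
replicates, days 11–39, 200×200 px scenes). In simulated scenes the
plant is drawn with `scene.pixels_per_kpix` pixels per kilopixel of
model biomass (top view taking `scene.top_share`), so image-derived
`EB` tracks the generating curve up to a known scale factor — which
leaves breakpoints, onset and ranking unchanged.

The analyze stage determines the onset day from the fitted breakpoints,
clamps it into the observed day range (with a warning) if the fits place
it outside, computes per-plant RGR between the onset and the last
observed day, joins water and reflectance records when present, and
writes the ranked vigour table with ANOVA columns and a correlation
report.

## Problem sizes and numerical choices

The test suite exercises the full image pipeline on a reduced cohort —
8 early-breakpoint genotypes × 4 replicates × 10 days (17–26 DAS) at
200×200 px — a size chosen to keep the whole suite comfortably fast
while spanning every breakpoint in the window; model-level checks (round
trips, fit quality, rank recovery) always use the complete 44-genotype
panel at days 11–39. Monte-Carlo checks use 10,000 replicates for the
noise-model mean and 1,000 samples for the Tukey flag rate.

Key numerical conventions, in one place: breakpoint grid 0.01 day with
smallest-X tie-break; degenerate (collinear) series flagged rather than
failed; adjusted $R^2$ with $p = 4$; hull rasterization over pixel
squares with closed-hull membership (tolerance $10^{-9}$, scaled);
8-connected components; type-7 quartiles; kilopixel = pixel count /
1000.

## Known limitations

* The colour rule assumes the scene's colour separation; it is not a
  general plant segmenter and will misclassify scenes with green or
  blue backgrounds, specular highlights or strong colour casts.
* Overlapping leaves are invisible to pixel sums; on real plants `EB`
  systematically under-measures large canopies.
* One breakpoint only; genotypes with more complex trajectories
  (e.g. logistic saturation within the window) are approximated, not
  modelled.
* s.e.d./LSD assume the one-way, (near-)balanced design; blocked or
  spatial analyses are out of scope.
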