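---
title: "phenocf: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenocf: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocf)
```

This vignette documents the scientific content of `phenocf`: the measurement
protocol it encodes, the formulas and statistics it computes, the generative
model behind its simulator, and the places where a convention had to be
fixed because the field leaves it open. It states no empirical result that
the package's tests and acceptance script do not themselves compute.

## The measurement protocol

A chlorophyll-fluorescence induction series on a dark-adapted plant
proceeds: measure minimal fluorescence F~O~; apply a saturating pulse to
measure maximal fluorescence F~m~; after a short dark relaxation, switch on
actinic light, capturing the Kautsky peak F~p~ at 16 s; at 25, 38, 50, 62
and 74 s measure the instantaneous fluorescence F~T~, a saturating pulse
gives the light-adapted maximum F'~m~, and a far-red exposure the
light-adapted minimum F'~O~ (74 s is treated as the steady state); after
20 s of darkness (85 s) F~O~, F~m~ and F~T~ are measured again.

`cf_schedule()` enumerates this protocol: 21 measured captures and 34
calculated parameter images, 55 transient measures over 13 parameter
families. Two decompositional choices deserve note:

* The instantaneous quantum yield Q~y~ is scheduled at the five light
  timepoints *and* at 85 s (like NPQ and qP), which is the unique
  itemization of the narrative above that sums to 55.
* The maximum PSII quantum yield is sometimes listed separately as
  "Q~y,max~"; it is formula-identical to F~v~/F~m~ and is treated as an
  alias, not a 56th measure.

Labels follow `<family>[_<seconds>]` with light-adapted (primed) families
suffixed `_L` (`Fm_L_25`, `FvFm_L_74`), the dark-adapted state unsuffixed
(`F0`, `Fm`, `FvFm`), and the Kautsky peak plainly `Fp`. Apostrophes are
deliberately absent so labels double as file names.

## Parameter formulas

The engine evaluates, pixel by pixel,

| Parameter | Formula | Note |
|---|---|---|
| F~v~/F~m~ | (F~m~ − F~O~)/F~m~ | dark-adapted |
| F'~v~/F'~m~(t) | (F'~m~(t) − F'~O~(t))/F'~m~(t) | |
| NPQ(t) | (F~m~ − F'~m~(t))/F~m~ | F~m~(85) replaces F'~m~ at 85 s |
| qP(t) | (F~m~ − F~T~(t))/(F~m~ − F~O~) | dark-adapted F~m~, F~O~ |
| qL(t) | qP(t) · F'~O~(t)/F~T~(t) | |
| Q~y~(t) | (F~m~ − F~T~(t))/F~m~ | |
| R~FD~(t) | (F~p~ − F~T~(t))/F~T~(t) | |

NPQ, qP and Q~y~ here use dark-adapted denominators, which differs from the
textbook conventions (NPQ is usually normalized by F'~m~, qP by
F'~m~ − F'~O~). The protocol forms are implemented verbatim as the
instrument software defines them; the textbook variants are available via
`conventional = TRUE` in `compute_parameter()`. The discrepancy is
documented rather than silently "fixed", because the global-value and
clustering screens only need a consistent convention, not a particular one.

**Invalid pixels.** A ratio with denominator exactly 0 is masked (`NA` plus
a logical mask); `strict = TRUE` additionally masks negative numerators or
denominators, which on real data flags sensor artifacts. Masked pixels are
excluded from global means and histograms — NaN propagation would otherwise
poison every whole-image statistic. No clamping of parameter values to
[0, 1] is performed.

## Global-value statistics

The *global value* of an image is the arithmetic mean of all its pixels
(for calculated images: all unmasked pixels); backgrounds are deliberately
included for measured captures, taking the plain definition literally.
Treatments are compared per measure by the two-sided Mann–Whitney *U* test,
U = #{(i,j): a~i~ > b~j~} + ½·ties, with

* an exact p-value (equivalent to full enumeration of rank assignments)
  when n~a~ + n~b~ ≤ 12 and there are no ties,
* otherwise the normal approximation with tie and continuity corrections;
* significance codes `**` (p < 0.01), `*` (p < 0.05), strict inequalities;
* no multiple-testing correction across the 55 measures by default (each
  measure is read as its own screen); `p_adjust` in `compare_all()` offers
  Bonferroni/FDR variants.

Box-plot summaries use type-7 quantiles (linear interpolation between order
statistics), the R default, fixed for reproducibility. Radial plots are
split into four magnitude panels at 1, 25 and 300 because raw fluorescence
(hundreds to thousands of ADU) and ratio parameters (≤ 1) cannot share an
axis; boundary values are assigned to the upper panel (half-open
intervals), and negative means — possible for noisy calculated images —
warn and fall into the first panel.

## Histogram distances and clustering

Each image is reduced to a histogram. Measured captures use 256 uniform
bins over the sensor range [0, 4096); calculated (ratio-valued) images have
no fixed range, so one analysis shares a single grid spanning the observed
min/max across the compared set — Bhattacharyya comparison requires a
common grid. Bins are half-open `[e_k, e_{k+1})` with a closed last bin.
Instrument-exported histogram files with unequal grids are rebinned onto
their common edge refinement, distributing counts proportionally to
overlap.

The Bhattacharyya coefficient of two normalized histograms is
BC = Σ~k~ √(p̂~k~ q̂~k~) ∈ [0, 1], 1 exactly when the distributions
coincide (the Cauchy–Schwarz equality case). As the clustering distance the
package fixes the Hellinger form d = √(1 − BC): it is a true metric,
bounded in [0, 1], which keeps agglomeration heights interpretable; the
unbounded Bhattacharyya distance −ln BC remains available behind
`kind = "bhattacharyya-log"`.

Agglomeration supports the six classical Lance–Williams methods — single,
complete, UPGMA (`average`), WPGMA (`mcquitty`), WPGMC (`median`), UPGMC
(`centroid`) — via `stats::hclust` behind the `linkage()` surface. The two
geometric methods are applied on squared distances with square-root heights
reported, and may produce height inversions (counted on the result). The
test suite proves equivalence of all six methods with an independent naive
O(n³) agglomerator on hundreds of random matrices, and the Gower–Ross
property (single-linkage heights = sorted MST edge weights) against an
independent spanning-tree implementation.

**Cutting and scoring.** Dendrograms are cut into k groups by undoing the
last k − 1 merges *in merge order* — robust to inversions, unlike a height
cut — with k defaulting to the number of distinct ground-truth labels
(k = 2 for control vs inoculated, mirroring the two-major-branch reading of
such dendrograms). The mis-clustering rate maps clusters to labels by the
best permutation and reports the minimized error fraction; with k = 2 the
rate is therefore bounded by 0.5, and a label-blind clustering hovers just
below that bound.

## The simulator

The simulator exists to exercise the pipeline with known ground truth, not
to model leaf optics. Each plant is a rosette of `n_leaves` elliptical
leaves plus a central disc on a dark background. Per-pixel latents on the
rosette:

* F~O~ ~ lognormal with mean `f0_mean` (400 ADU) and CV `f0_cv` (0.15);
* F~v~/F~m~ = `fvfm0` (0.80, the canonical healthy value) reduced by the
  stress effect; F~m~ = F~O~/(1 − F~v~/F~m~);
* NPQ induction F'~m~(t) = F~m~(1 − NPQ~∞~(1 − e^(−t/τ~NPQ~))), with
  NPQ~∞~ = 0.35, τ~NPQ~ = 30 s;
* photochemical quenching qP(t) = qP~ss~ + (1 − qP~ss~)e^(−t/τ~qP~), with
  qP~ss~ = 0.55, τ~qP~ = 20 s, giving F~T~(t) = F~m~ − qP(t)(F~m~ − F~O~);
* F'~O~(t) = F~O~ F'~m~(t)/F~m~, and F~p~ = F~O~ + 0.9 (F~m~ − F~O~);
* dark relaxation at 85 s recovers a fraction `relax` (0.8) of the
  quenching: F~m~(85) = F~m~(1 − (1 − relax)NPQ~∞~(1 − e^(−74/τ~NPQ~))),
  F~T~(85) = F~O~ + (1 − relax)(F~T~(74) − F~O~), F~O~(85) = F~O~.

These kinetic forms are chosen so that inverting the engine's printed
formulas at zero noise recovers the configured values *exactly*:
F~v~/F~m~ directly, NPQ~∞~ = NPQ(t)/(1 − e^(−t/τ~NPQ~)), and
qP~ss~ = (qP(t) − e^(−t/τ~qP~))/(1 − e^(−t/τ~qP~)) — which is what the
acceptance checks assert to 10⁻⁶ per pixel (with quantization off; the
12-bit rounding otherwise adds ~10⁻³ relative error, still far inside the
0.01 tolerance used for noisy group means).

Stress multiplies F~v~/F~m~, qP~ss~ and NPQ~∞~ by (1 − δ·stress(x, y)) over
the lesioned leaves (`lesion_fraction` of the rosette; 1 = systemic). The
default inoculated group carries δ~qP~ = 0.5, δ~NPQ~ = 0.3,
δ~FvFm~ = 0.05 — a strong systemic effect on photochemical quenching with
a mild effect on the dark-adapted yield, the pattern a root parasite
drawing on the host's assimilate stream would produce. Plant-to-plant
variability (lognormal `plant_cv` = 0.1 on F~O~, jitter `plant_cv`/10 on
the three parameters) makes the group comparisons honest. Every capture
receives multiplicative Gaussian noise (σ = 0.05 by default), clamping to
[0, 2^12) and integer quantization. With probability
`inoculation_failure` (default 0; opt-in) an inoculated plant is generated
healthy and flagged, so "apparent health" can diverge from the treatment
label as it does in real inoculation experiments.

The background is a near-zero dark offset (2 ADU). This keeps background
denominators of the ratio parameters at exactly zero after quantization, so
backgrounds are masked out of calculated images rather than contributing
wild ratio outliers; for measured captures the background contributes a
common spike that cancels in treatment comparisons.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: OJIP fine structure within the induction rise,
leaf-angle and chlorophyll-content gradients, specular reflections, moving
leaves between captures, and instrument vignetting. Tests against the
simulator validate the pipeline's arithmetic and statistics, not the
biology of any particular stressor.

## Numerical and design choices

* **Problem sizes.** The default simulated frame is 64 × 64 px (the full
  512 × 512 sensor via `size = 512L`); the bundled analyses and acceptance
  checks run 15-vs-15 studies at 64 × 64 and 200 random 8-point matrices
  for the linkage oracle — sizes chosen so the whole suite re-runs in
  about a minute while keeping ≥ 4000 pixels per image for stable means.
* **Tie-breaking.** Agglomeration ties are broken toward the
  smallest-index pair (continuous random distances make ties measure-zero;
  the rule only matters for degenerate inputs, which `cluster_all_measures`
  flags).
* **Determinism.** One integer seed fixes a simulation; plant-level latents
  derive from (seed, ecotype, group, plant) so a plant keeps its identity
  across imaging days, while capture noise re-derives per day. All derived
  seeds stay below 2³¹.
* **TIFF container.** 16-bit unsigned single-channel, no compression;
  12-bit values stored as-is, round-tripping bit-exactly. Calculated
  images written to disk use a fixed per-family integer scale (recorded in
  `parameter_scales.csv`) so stored copies remain comparable across
  plants; analyses nevertheless recompute calculated parameters from the
  measured captures.
* **Histogram text dialect.** `<bin><TAB><count>` lines with `#` comments;
  parse errors carry line numbers.
* **Contact sheets.** 1–99 % percentile contrast stretch computed over the
  *whole sheet*, never per panel — cross-panel comparability is the
  sheets' purpose; the shared range is recorded in the render metadata.

## Known limitations

* Numeric agreement with any specific instrument vendor's exported
  parameter images (which may clamp or rescale) is not claimed.
* The exact-test switch (n ≤ 12, no ties) is a convention; other software
  switches at different sizes, so p-values near the switch boundary can
  differ in the third decimal from other implementations.
* `misclustering_rate` searches label permutations and is limited to 8
  distinct labels; beyond that an assignment solver would be needed.
* Rendering aims at screening quality, not publication figures.
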