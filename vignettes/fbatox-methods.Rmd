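---
title: "Methods: single-cell FBA accumulation and cytotoxicity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell FBA accumulation and cytotoxicity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbatox)
```

## The measurement problem

Cultured primary hepatocytes take up fluorescent bile acid (FBA, a
fluorescein-coupled chenodeoxycholate) through their organic-anion
transporters. Per-cell FBA accumulation is highly heterogeneous, and that
heterogeneity carries information: cells that accumulate more FBA also
accumulate more of the hydrophobic bile acids that kill them. Quantifying
this requires (i) finding each cell without a membrane marker, (ii)
measuring its cytosolic fluorescence in a reproducible region, (iii)
rejecting dead cells, damaged cells and debris by explicit quantitative
rules, (iv) calling death over a 30-hour propidium-iodide (PI) time-lapse,
and (v) relating per-cell death to initial FBA by tertile stratification.
`fbatox` implements this measurement chain end to end, plus a synthetic
field generator that provides ground truth for every stage.

## Nuclear segmentation

Nuclei are segmented from the Hoechst channel only. Two enhancement
variants are provided, selectable per assay:

* **spot** (default): a spot-enhancing filter — Gaussian smoothing at scale
  $\sigma$ followed by a discrete 4-neighbour Laplacian, scale-normalized
  by $\sigma^2$ and sign-flipped so bright blobs give positive peaks;
* **smooth**: plain Gaussian smoothing, appropriate for sparse fields
  where the halo of a smoothed nucleus cannot touch its neighbour's.

The enhanced image is thresholded automatically with the **triangle
method**: on the 256-bin histogram, a line is drawn from the peak to the
farthest nonzero bin on the longer-tail side, and the threshold is the bin
at maximal perpendicular distance from that line. Tie-breaking is
deterministic and documented: among equally distant bins the middle of the
tied run wins, and with equally long tails the right tail is used. Binary
components are hole-filled and labelled 4-connectedly; **no size or shape
filtering happens at segmentation time** — malformed objects are removed
later by the exclusion rulesets, which keeps the segmentation stage free
of hidden thresholds.

The filter scale defaults to `sigma_um = 2`. A classic matched filter for
a radius-$r$ blob would use $r/\sqrt 2 \approx 3.5\,\mu m$ for the
$\approx 5\,\mu m$ nuclei this assay targets, but at plating density
(1200 cells/mm²) nearest-neighbour nuclei can sit ~1 µm apart and the
matched scale merges them; $2\,\mu m$ keeps the positive response compact,
and on the standard synthetic field recovers nuclei with recall and
precision above 0.99. Both the scale and the mode are plain config values.

## Shape metrics

* **Area** is `pixel_count * pixel_size_um^2`.
* **Nuclear diameter** is the maximum Feret diameter: the largest
  center-to-center distance between boundary pixels, computed exactly via
  the convex hull (the diameter of a point set is attained on its hull).
* **Circularity** is $4\pi A / P^2$. The perimeter $P$ comes from Moore
  tracing of the outer contour with weighted step lengths (0.948 per
  axial, 1.340 per diagonal step). A naive pixel-edge count would
  overestimate a disk's perimeter by ~27% and push its circularity to
  ~0.62 — right at the 0.6 debris cutoff — so a low-bias estimator is not
  cosmetic here; with these weights large rasterized disks measure within
  a few percent of 1. On very small discrete masks circularity may exceed
  1; the rulesets only use lower cutoffs, so this is harmless.

## The cytosolic annulus

Cell fluorescence is measured in an annular "cellular ROI" from the
nuclear border to 3 µm beyond it. The annulus is purely geometric and
membrane-agnostic: a pixel within 3 µm of two nuclei is assigned to the
nearer one (ties to the lower label), and annuli are clipped at field
edges. Distances are Euclidean between pixel centers, with 0-based
(row, col) coordinates and a top-left origin. The band width is a
parameter (`band_um = 3`).

## Backgrounds

Anion (FBA) intensities are corrected by subtracting the mean cytosolic
intensity of a vehicle control imaged without fluorescent anion; Hoechst,
Lysotracker and PI are corrected by subtracting the field's modal pixel
value. Corrected values keep their sign — clamping at zero would bias
condition means upward exactly where signal is weakest. Condition means at
or below 75 a.u. are annotated as too low for robust scoring (a reporting
annotation, not a per-cell filter).

## Exclusion rulesets

Three named, declarative rulesets reproduce the assay variants' thresholds
exactly; each rule is a row (statistic, ROI, channel, relation, bound) and
every bound is overridable in the run configuration:

| ruleset | rules |
|---|---|
| `accumulation_assay` | anion cytosol SD >×15 or <÷15 of the population mean SD; Lysotracker cytosol SD >×10 or <÷5; Hoechst nuclear SD >×2.5 or <÷5; nuclear Lysotracker mean >×1.5; nuclear area <47 or >360 µm²; circularity <0.6 |
| `viability_assay` | area outside (36, 468) µm²; nuclear PI ≥200 a.u.; Hoechst nuclear SD >×2 or <÷2; circularity <0.6 |
| `timelapse_assay` | area outside (36, 252) µm²; circularity <0.05 |

Two readings of "mean × k" are implementable; the default compares a
cell's statistic to the **population mean of that statistic**, computed
once over all candidate records of the same condition/time point before
any flagging. This makes flagging deterministic, idempotent and
order-independent (no iterative re-computation, no dependence on record
order), which the test suite verifies against a brute-force re-evaluation.
The alternative reading — comparing a cell's SD to its *own* mean
intensity — is available via `reference = "self"`. SD rules are assigned
to each dye's target compartment: anion and Lysotracker to the cytosol
ROI, Hoechst to the nuclear ROI.

A consequence of the population-relative design worth knowing: the
reference is only meaningful when gross outliers are rare. If a large
fraction of candidate objects have extreme SDs (e.g. a field dominated by
bright speckled debris), the population mean shifts and ordinary cells can
be flagged as "too smooth". The generator's debris and dead-cell
intensities are therefore calibrated to realistic contrast (debris at
roughly nuclear brightness, dead-cell Hoechst SD a few-fold the live
value), not to arbitrary extremes.

## Time-lapse death calling

ROIs are segmented once, on frame 1, and frozen: the fields are re-imaged
in place every 10 min for 30 h (181 frames) and hepatocytes are
essentially non-motile on that scale, so tracking would add failure modes
without information. Per frame, PI and FBA are measured in the frame-1
cellular ROI and the per-frame image mode is subtracted. A cell dies at
the first frame where PI cell fluorescence exceeds 100 a.u. above
background; which ROI carries "cell fluorescence" is configurable
(`pi_roi`), defaulting to the cytosolic annulus. `fba_over_hoechst`
normalizes frame-1 FBA to nuclear Hoechst; cells with non-positive
corrected Hoechst get an undefined ratio and are excluded.

## Stratification and population statistics

Retained, frame-1-viable cells are sorted by initial FBA and split into
three contiguous groups of equal size (remainders to low, then mid; ties
keep stable order). Reported per group: n, death percentage, mean FBA,
SEM, CV. Because the customary statement "high accumulators died k% more
than the whole population" is ambiguous between absolute percentage
points and relative fractions, the summary reports both, labelled
`death_diff_vs_whole_pts` and `death_diff_vs_whole_rel`.

Other statistics follow the field's standard conventions: CV uses the
sample (n−1) SD over the mean; correlations are Pearson product-moment;
time-course summaries treat the **experiment** as the unit of replication
(mean of per-experiment means, SEM = SD/√n, classic equal-variance
two-sided Student's t-test); fold-changes are ratios of background-
corrected condition means with no log transform. The power law
$y = a x^b$ is fitted by least squares on $\log y = \log a + b \log x$ —
deterministic, exact on noiseless data — with an optional raw-scale
`nls()` refinement behind a flag.

## The synthetic field generator

The generator emulates the statistical structure the analysis assumes, at
the standard study conditions:

* **Geometry**: 770×770 px at 0.65 µm/px (0.25 mm²; pixel size is always
  an explicit parameter since objective magnification varies between
  experiments). Cell count is Poisson with mean `density × area`
  (default 1200 cells/mm² ≈ 300 cells/field); centers are rejection-
  sampled with minimum separation `r_i + r_j + 1 µm`. Touching-nucleus
  stress tests are opt-in via `min_sep_extra_um <= 0`.
* **Intensity model**: signal = background (100 counts) + object profile,
  optional Poisson shot noise, Gaussian read noise added last, rounded and
  clipped to 16-bit. Nuclei are soft-edged disks (radius 5.0 ± 0.3 µm,
  truncated at 3 SD) in Hoechst; FBA and Lysotracker are uniform over each
  cell's footprint out to 5 µm beyond the nuclear border. Each pixel takes
  the amplitude of the **nearest** cell rather than an additive mixture —
  confluent hepatocytes tile the substrate, they do not superimpose — and
  the footprint deliberately exceeds the 3 µm measurement band so
  segmentation jitter cannot push the annulus onto background.
* **Heterogeneity**: per-cell FBA amplitudes are lognormal with
  σ = 0.15 (CV ≈ 15%, inside the 13–21% range characteristic of 3D
  culture); Hoechst and Lysotracker amplitudes are truncated-normal with
  ~8% CV. For immunofluorescence-correlation studies the Lysotracker slot
  carries a marker whose log-scale correlation with FBA is `marker_rho`.
* **Dead cells and debris**: dead cells get a fragmented (four
  overlapping-lobe) speckled nucleus, elevated PI over the whole cell
  (400 a.u. over background vs 10 for live cells) and reduced circularity;
  debris are sub-nuclear bright specks (area ≲ 8 µm², well under the 36
  and 47 µm² cutoffs). Together the standard fixture exercises the PI,
  SD, area and circularity rules.
* **Death model**: a cell alive at frame 1 dies in any later frame with
  probability `plogis(alpha + beta (log F - mu))`, with per-frame log-odds
  `alpha = -5.5` at the median FBA and coupling `beta = 2.2` per unit
  log-FBA. Over 180 at-risk frames these defaults give ~50% whole-
  population death with the high tertile ~13 points above the whole
  population — the magnitude regime of a hydrophobic-bile-acid challenge.
  `beta = 0` is the exact null. After death, PI steps to the dead level
  and FBA decays by 3% per frame.

`generate_timelapse(render = FALSE)` draws per-cell traces from the same
stochastic model without rasterizing frames; population-scale studies
(thousands of cells × 181 frames) use this path, while `render = TRUE`
produces full four-channel TIFF sequences for pipeline-level tests at
smaller sizes. Every run is bit-reproducible from `rng_seed`, and the
caller's RNG state is left untouched.

What the generator does **not** emulate: optics-grade PSFs, collagen-layer
scattering, bile-canalicular structures, cell migration, focus drift, or
photobleaching. Passing tests therefore demonstrate that the measurement
chain is correct under the stated statistical model, not that it is robust
to every artifact of real microscopy.

## Numerical choices and degenerate inputs

* All filters use mirror reflection at image boundaries (edge pixel not
  duplicated), so flat fields stay exactly flat.
* Integer images get exact per-value histograms; float images 256 equal
  bins over the observed range.
* The image mode rounds pixels to integers and breaks ties toward the
  smallest value.
* A blank Hoechst image (degenerate histogram) yields zero nuclei and a
  warning, not an error; empty masks, empty record lists, missing
  channels, and histograms with fewer than two nonzero bins raise typed
  errors.
* Contested annulus pixels tie to the lower label; equal-distance triangle
  candidates tie to the middle of the run; tertile remainders go to low,
  then mid.

## Problem sizes used in the shipped checks

The packaged validation uses: ~300-cell fields (0.25 mm²) for
segmentation recovery; ~45-cell fields for rendered time-lapse tests
(12–25 frames); 1467–2000 cells at 181 frames, trace-level, for
stratification against a 200,000-draw Monte-Carlo oracle of the same
hazard; 200 replicates for null-correlation and power-law recovery. These
sizes give every comparison its stated statistical resolution while
keeping the whole suite under a minute.

## Known limitations

* Touching nuclei are not split (no watershed): the segmentation stage is
  deliberately enhancement + threshold only, and merged objects are left
  to the area/circularity rules, mirroring the assay's original design.
* The population-relative SD rules assume outliers are a minority of
  candidates (see above).
* Time-lapse ROIs are frame-1-frozen; motile cell types would need
  tracking.
* The smooth enhancement variant is only reliable on well-separated
  fields; the spot variant is the default everywhere.
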