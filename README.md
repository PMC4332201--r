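# fbatox

Automated single-cell image analysis of fluorescent bile acid (FBA)
accumulation and cytotoxicity in cultured hepatocytes.

Primary hepatocytes take up fluorescein-coupled bile acid through their
organic-anion transporters, and how much each cell accumulates predicts
how vulnerable it is to hydrophobic-bile-acid toxicity. `fbatox` is for
researchers running high-content assays on such cultures: it turns
multi-channel fluorescence fields (Hoechst / anion / Lysotracker /
propidium iodide) into per-cell measurements, quality-filtered
populations, death calls, and tertile-stratified cytotoxicity statistics.

The measurement chain:

1. **Segment nuclei** from Hoechst with a spot-enhancing
   (Laplacian-of-Gaussian) or smoothing filter and automatic **triangle
   thresholding** of the enhanced histogram.
2. **Build the cellular ROI**: the annulus from the nuclear border to
   3 µm beyond it; contested pixels go to the nearest nucleus.
3. **Measure** mean / SD / integrated intensity per channel per ROI;
   subtract the vehicle-control mean (anion) or the image mode (other
   channels).
4. **Exclude** damaged cells and debris with declarative rulesets, e.g.
   for accumulation assays: SD outliers per channel (anion > ×15 or < ÷15
   of the population mean SD, Lysotracker > ×10 or < ÷5, Hoechst > ×2.5 or
   < ÷5), nuclear Lysotracker mean > ×1.5, nuclear area outside
   (47, 360) µm², circularity 4πA/P² < 0.6. Viability scoring and
   time-lapse variants use their own documented bounds.
5. **Call death** in 10-min / 30-h PI time-lapses: a cell dies at the
   first frame its background-subtracted PI cell fluorescence exceeds
   100 a.u. (ROIs frozen at frame 1).
6. **Stratify** cells into low / mid / high FBA tertiles and report death
   percentages, dying-vs-surviving FBA fold, CV (SD/mean), per-cell
   Pearson correlations, time-course summaries (SEM over experiments,
   Student's t-tests), and power-law fits *y = a·x^b*.

A synthetic field generator (`generate_field()`, `generate_timelapse()`)
renders hepatocyte-like multi-channel 16-bit fields — lognormal
cell-to-cell FBA heterogeneity, dead-cell phenotypes, debris, an
FBA-coupled logistic death hazard — together with a ground-truth table, so
every stage of the pipeline is testable against known truth.

## Worked example

Run the packaged time-lapse demo (a small synthetic field, 19 frames at
10-min intervals, FBA-coupled death hazard):

```r
library(fbatox)
demo <- system.file("extdata", "demo_timelapse.yaml", package = "fbatox")
res <- run_pipeline(demo)
res$summary
#>  n_segmented n_analyzed death_pct_whole fold_fba_dying_vs_surviving
#>           29         28        57.14286                    1.098803
res$groups[, c("group", "n", "death_pct", "mean_fba", "cv_pct")]
#>  group  n death_pct mean_fba cv_pct
#>    low 10     50.00    440.8  6.183
#>    mid  9     44.44    505.2  7.456
#>   high  9     77.78    654.7  5.337
#>  whole 28     57.14    530.3 18.244
```

Reading the output: 29 nuclei were segmented on frame 1; 28 passed the
exclusion rules, were PI-negative at frame 1 and had a defined
FBA/Hoechst ratio. 57.1% of them died within the observation window, and
death concentrates in the high-FBA tertile (77.8% vs 50.0% in the low
tertile; dying cells had 1.10-fold higher initial FBA than survivors).
`mean_fba` is the background-subtracted mean initial FBA per tertile in
a.u.; `cv_pct` the within-group coefficient of variation. With
`run_pipeline(demo, outdir = "out")` the run writes `cells.csv`,
`groups.csv`, `summary.csv`, `exclusion_census.csv`, `report.json`, a
label-map TIFF and a copy of the resolved configuration; rerunning with
the same seed reproduces every file byte-for-byte.

The other assay variants are `accumulation` (vehicle-corrected per-cell
FBA with the full outlier ruleset), `viability` (per-field viable-cell
counts) and `if_correlation` (per-cell correlation of FBA with an
immunofluorescence marker). A thin CLI wraps the same functions:

```sh
Rscript inst/cli/fbatox.R run --config inst/extdata/demo_timelapse.yaml --outdir out
Rscript inst/cli/fbatox.R simulate --outdir sim --seed 1
```

See `vignettes/fbatox-methods.Rmd` for the full model description,
parameter defaults, and design rationale.

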