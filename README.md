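# tractshift

Paired pre- versus intraoperative diffusion-MRI tractometry, with a
synthetic fiber phantom for end-to-end validation.

## What it does, and for whom

Neurosurgical teams and imaging researchers can acquire diffusion MRI
both before a craniotomy and intraoperatively, reconstruct a tract of
interest at both timepoints, and ask how much surgery changed it. The
package implements that comparison for the dentato-rubro-thalamic tract
(DRTT) — the cerebellar output pathway from the dentate nucleus via the
thalamus to the motor cortex, split into its decussating (d-DRTT) and
non-decussating (nd-DRTT) components — with the arcuate fasciculus (AF)
as a distant control tract:

* **Tracking** — deterministic FACT propagation over discrete
  fiber-peak fields: 1-mm seed lattice over the brain mask, 1-mm steps,
  termination when the peak amplitude drops below 0.01, the turn angle
  exceeds 60°, or the position leaves white matter.
* **Gating** — AND/NOT ROI waypoint logic (dentate, thalamus, motor
  cortex; corpus callosum and tumor exclusion), d-/nd-DRTT
  classification by the motor-end vertex, and a cohort-level
  normalized-median-length filter for the AF.
* **Tractometry** — tract volume as visited voxels (normalized to
  supratentorial white-matter volume), diameter
  `2·sqrt(volume/(π·length))`, whole-tract FA/MD averaged across
  streamlines, and 55-segment along-tract FA/MD profiles by
  nearest-centerline-segment projection
  (`ceiling(138 mm / 2.55 mm) = 55`).
* **SNR** — per-voxel temporal mean/SD of the b=0 volumes, averaged
  over white matter.
* **Statistics** — paired Wilcoxon and linear mixed-effects models
  (patient random intercept; age- and SNR-adjusted variants), paired
  Cohen's d with 0.2/0.5/0.8 bands, rank-sum group contrasts by a
  speech-disturbance label, logistic regression of the label on age and
  sex, per-segment mean-change tests with Benjamini–Hochberg control,
  and Pearson correlation of tract change against ventricular or tumor
  volume.
* **Phantom** — paired synthetic subjects (two-shell 6/20/32 scheme,
  2.55-mm voxels, Rician noise) with known injected effects: bundle
  compression, localized MD elevation near the dentate end, SNR
  reduction, and a linked speech label. Ground truth is recorded with
  every pair.

## Worked example

Simulate a small cohort with the injected alteration (radius scale 0.7
and a localized MD elevation on the left d-DRTT, SNR scale 0.906) and
run the battery:

```r
library(tractshift)
cfg <- studyConfig("alteration", simulateRegion = "tracts")
co  <- simulateCohort(cfg, n = 8, seed = 7,
                      params = studyTrackingParams(), micro = TRUE)
bat <- runStatsBattery(co)

head(co$metrics[, c("subject","timepoint","tract","volumeNorm",
                    "diameterMm","faMean","mdMean")], 4)
#>    subject timepoint  tract volumeNorm diameterMm    faMean       mdMean
#> 1 S7000022       pre d_DRTT   18.46225   10.88485 0.7652696 0.0007469646
#> 2 S7000022     intra d_DRTT   15.77228   10.00269 0.7466689 0.0007622316
#> 3 S7000023       pre d_DRTT   18.76410   11.27462 0.7637463 0.0007490155
#> 4 S7000023     intra d_DRTT   15.18756   10.07429 0.6979790 0.0008074099

bat$paired[, c("tract","metric","percentChange","pWilcoxon","pLmm","d","band")]
#>    tract     metric percentChange  pWilcoxon         pLmm          d     band
#> 1 d_DRTT volumeNorm   -15.9692352 0.00781250 1.852168e-68 -6.1820108    large
#> 2 d_DRTT diameterMm    -9.0303873 0.00781250 3.583551e-83 -6.8309693    large
#> 3 d_DRTT     faMean    -5.9123810 0.01562500 1.582061e-04 -1.3356618    large
#> 4 d_DRTT     mdMean     5.7190086 0.01562500 3.866367e-04  1.2547753    large
#> 5     AF volumeNorm    -2.9417041 0.10937500 2.479247e-02 -0.7935934 moderate
#> 6     AF diameterMm    -2.8381266 0.02770785 5.329130e-04 -1.2245828    large
#> 7     AF     faMean    -0.3009679 0.19531250 1.209331e-01 -0.5185514 moderate
#> 8     AF     mdMean    -0.3722955 0.14843750 8.450984e-02 -0.6099142 moderate

aggregate(pFdr ~ tract + metric, bat$segments,
          function(p) sum(p < 0.05, na.rm = TRUE))
#>    tract metric pFdr
#> 1     AF     FA    0
#> 2 d_DRTT     FA   19
#> 3     AF     MD    0
#> 4 d_DRTT     MD   16
```

Reading the output: the compressed d-DRTT loses ~16 % of its normalized
volume and ~9 % of its diameter (paired p < 0.05, large effects), its
whole-tract MD rises ~6 %, and 16–19 of its 55 along-tract segments
show BH-significant FA/MD change — while the distant AF control stays
microstructurally flat (no significant segments) with only small global
macrostructural drift. `co$subjects` carries the ground truth
(`truthVolumeScale`, `truthMdDelta`, `truthSnrScale`), the measured
per-subject SNRs, and the speech labels; `runPipeline()` writes the
whole artifact tree (NIfTI maps, per-tract TCK files, metric and
profile CSVs, statistics tables) for a cohort.

## Package layout

S4 classes (`AcquisitionScheme`, `PeakVolume`, `StreamlineSet`,
`TensorMap`, `TractProfile`, `SubjectPair`) with accessors and show
methods; module surfaces in `R/phantom.R`, `R/dwi.R`, `R/tracking.R`,
`R/gating.R`, `R/tractometry.R`, `R/stats.R`, `R/io.R` (NIfTI,
FSL bval/bvec, MRtrix TCK, CSV/YAML), `R/pipeline.R` and `R/studies.R`;
the FACT inner loops are Rcpp. The methods vignette
(`vignettes/tractshift-methods.Rmd`) documents the model, parameter
choices, numerical conventions and limitations.
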