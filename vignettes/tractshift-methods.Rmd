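---
title: "Paired pre/intraoperative tractometry with a synthetic fiber phantom"
author: "tractshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired pre/intraoperative tractometry with a synthetic fiber phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractshift)
```

## The problem

Resection of a posterior fossa tumor can disturb the
dentato-rubro-thalamic tract (DRTT), the cerebellar output pathway from
the dentate nucleus through the thalamus to the motor cortex, and such
disturbance is a candidate mechanism for postoperative cerebellar mutism
and its speech symptoms. Comparing tractography between a preoperative
and an intraoperative diffusion MRI acquisition makes it possible to
quantify how much a tract changed *during* surgery: macrostructurally
(tract volume and diameter) and microstructurally (fractional anisotropy
FA and mean diffusivity MD, whole-tract and along the tract). The
arcuate fasciculus (AF), far from the surgical field, serves as a
distant control tract.

`tractshift` implements this analysis end to end — deterministic FACT
tractography over discrete fiber-peak fields, ROI waypoint gating with
decussating/non-decussating DRTT classification, tract metrics and
55-segment profiles, white-matter SNR, and the paired/grouped
statistical battery — and pairs it with a synthetic fiber phantom that
emulates the paired acquisitions with *known* injected effects, so that
every stage can be validated without any patient data.

## The phantom

A synthetic subject is a pair of datasets on a shared isotropic grid
(default 26 × 30 × 34 voxels of 2.55 mm; a 66 × 77 × 87 mm field of
view scaled to a young child's brain). Bundles are tubes around smooth
spline spines through stylized control points:

* `d_DRTT`: rises from the dentate region, crosses the midsagittal
  plane in the brainstem segment, and ascends through the contralateral
  thalamus to the motor cortex;
* `nd_DRTT`: same origin and target side as its dentate;
* `AF`: an arc between the Wernicke and Broca regions.

Per subject, control points are jittered (SD 1.2 mm), the bundle radius
is scaled by ±10 %, and ventricle/tumor sizes vary. Within the tube,
each voxel carries one fiber peak tangent to the spine (amplitude 1,
so the FACT amplitude floor of 0.01 separates bundle from background
cleanly) and an axially symmetric tensor with eigenvalues 1.7e-3 and
0.3e-3 mm²/s; background white matter is isotropic at 0.7e-3 mm²/s with
zero-amplitude peaks; gray-matter end regions, ventricles (CSF) and the
tumor get isotropic tensors of their own. The DWI signal follows the
mono-exponential tensor model S = S0·exp(−b·gᵀDg) over a two-shell
scheme (6 × b=0, 20 × b=1000, 32 × b=2000 s/mm²) with Rician noise of
magnitude S0/SNR. The preoperative SNR defaults to 24.36.

The intraoperative dataset is the same anatomy regenerated with the
injected surgical effect:

* `volumeScale` (default 0.7 under the alteration condition) multiplies
  the bundle **radius** — compression;
* `mdDelta` adds to MD inside an arc-length window at the dentate end
  (default window the first quarter of arc length; the per-subject
  magnitude is drawn from N(0.3e-3, 0.2e-3) mm²/s truncated at 0, so
  the cohort shows *variance* of change concentrated near the dentate,
  the qualitative signature of interest);
* `snrScale` (default 0.906) multiplies the SNR, reproducing a ≈9.4 %
  intraoperative SNR drop;
* the tumor mask is emptied (complete resection).

A binary speech-disturbance label is TRUE when the applied `mdDelta`
exceeds 0.3e-3 mm²/s on a left-sided bundle (mirroring the observation
that the left dentate-end segment carries the symptom-related
variability), optionally with spontaneous-label noise. The full truth
record is stored with the pair, so recovery can always be checked
without re-deriving it from images.

### Field support around the bundle

FACT uses the fiber direction of the voxel the current position falls
in. A streamline running parallel to the bundle axis at lateral offset
*d* therefore consults voxels whose centers fluctuate up to about a
voxel half-diagonal (≈2.2 mm at 2.55 mm voxels) farther from the axis
than the streamline itself. With a hard-edged tube whose field stops at
the mask radius, every seed at offset greater than (radius − 2.2 mm)
eventually lands in a zero-amplitude voxel and terminates mid-course;
on an oblique or curved tube of any plausible radius this loses the
majority of seeds. The phantom therefore rasterizes the peak/tensor
field over a *support* tube extending `supportMarginMm` (default
3.5 mm) beyond the bundle mask radius (default 2 mm), with flat ends at
the spine endpoints. The mask — used for seeding checks, ground truth
and reporting — stays at the core radius; with the default margin,
essentially every in-mask seed traverses the full bundle (measured
≥98.5 % across subjects for both the DRTT and the AF).
`makeBundleField()` keeps `supportMarginMm = 0` as its default, which
produces the hard-edged tube where that is wanted (e.g., the geometric
recovery checks).

Emulated: paired acquisitions on a shared grid, two-shell protocol,
Rician noise and SNR drop, compression, localized diffusivity change,
failed-reconstruction accounting, cohort heterogeneity. **Not**
emulated: realistic anatomy, crossing fibers (one peak per voxel),
partial-volume and susceptibility/eddy artifacts, registration error,
brain shift as a spatial deformation (compression is a radius change,
not a displacement field). Passing tests on the phantom therefore
validates the *pipeline mechanics and statistics*, not tractography
accuracy on real brains.

## Tensor model and SNR

Tensors are fit by ordinary (unweighted) least squares on log-signal
using both shells — the reproducible baseline when the estimator is
otherwise unspecified; a voxel with any non-positive signal is marked
invalid, never imputed. Eigenvalues come from the closed-form symmetric
3 × 3 solution; negative eigenvalues are clamped to zero before FA/MD
and the clamp count reported. FA uses
√(3/2)·‖λ − MD‖/‖λ‖ ∈ [0, 1] (an all-zero tensor is defined to have
FA = 0), MD is the eigenvalue mean.

White-matter SNR is the mean over WM voxels of (temporal mean)/(temporal
sample SD, n−1 denominator) of the b=0 volumes; zero-SD voxels are
excluded and counted. With only six b=0 volumes this estimator is biased
high by ≈19 % (the 1/s moment of a χ distribution), which the tests pin
against a Monte-Carlo oracle; the *ratio* of pre to intra SNR — the
quantity the analysis uses — is unaffected by the bias.

## Tracking

Deterministic FACT: seeds on a 1-mm isotropic lattice (origin at the
mask bounding-box corner, x fastest ordering), 1-mm steps, termination
when the best-aligned peak's amplitude falls below 0.01, when the turn
angle between successive steps exceeds 60°, or when the position leaves
the white-matter mask (the exiting vertex is retained — the gray-white
interface criterion). The first step at a seed follows the voxel's
largest-amplitude peak in both signs and the two half-tracks are
joined. Peaks are sign-ambiguous and resolved into the incoming
hemisphere at every step; ties in peak alignment break toward the lower
peak index, making the tracker fully deterministic. Streamlines shorter
than two steps are dropped (degenerate seeds) and counted.

## Gating and tract definition

A streamline intersects an ROI when any vertex's containing voxel is
in-mask — a vertex test, adequate at 1-mm steps on 2.55-mm voxels.
Tracts are selected by AND/NOT waypoint logic (DRTT: dentate, thalamus
and combined motor-cortex inclusion; corpus callosum and tumor
exclusion; AF: Wernicke and Broca inclusion), oriented so vertex 1 is
nearest the dentate (or Wernicke) ROI, and the DRTT is partitioned by
the motor-end vertex: contralateral motor cortex → d-DRTT, ipsilateral
→ nd-DRTT, neither → unclassified (logged). Side labels follow the
dentate hemisphere. An empty gated set is a failed reconstruction and
is flagged, mirroring the failure accounting of real cohorts.

The AF length filter is cohort-level: per subject, the median AF
streamline length normalized by brain height (feet-head extent of the
brain mask); the threshold is the 1st percentile (linear interpolation
between order statistics, R type 7) of those normalized medians, and
each subject's streamlines below it are removed. Of the two readings of
the published procedure — thresholding subjects vs thresholding
streamlines — only the latter removes short spurious streamlines, so it
is implemented. Note a structural consequence: because the threshold
sits near the lowest cohort median, subjects whose whole length
distribution lies low can lose an appreciable share of genuine
streamlines; the filter's guarantee is exactly "remove everything below
the cohort threshold", which the tests assert against a truth-label
oracle.

## Tractometry

* Volume: count of voxels containing at least one streamline vertex ×
  voxel volume; normalized volume = 100 × volume / supratentorial WM
  volume.
* Diameter: 2·√(volume/(π·length)) with length the **mean** streamline
  length of the tract (the formula's "length" is otherwise undefined).
* Whole-tract FA/MD: per-streamline vertex means (nearest-voxel
  sampling, matching FACT's voxel-constant philosophy), then the
  unweighted mean across streamlines, so every streamline counts
  equally.
* Along-tract profiles: each streamline resampled to n+1 equidistant
  points; the centerline is the pointwise mean; every vertex is
  assigned to the nearest centerline segment midpoint (ties toward the
  lower index) and per-segment means are taken. Segment 1 sits at the
  dentate (Wernicke) end. n is fixed at 55 for all tracts and subjects
  — the value the ceiling rule gives for a 138-mm mean length at
  2.55-mm voxels, exposed as `nSegmentsRule()` — rather than recomputed
  per subject. Empty segments are NA, never zero-filled.

## Statistics

Paired pre/intra comparisons use the Wilcoxon signed-rank test (exact
for n ≤ 25 without ties, tie-corrected normal approximation otherwise)
and linear mixed-effects models with a patient random intercept, with
age- and SNR-adjusted variants reported side by side (the source
protocol alternates the covariate without tabulating which enters
where). The covariate-free balanced model's timepoint estimate equals
the mean paired difference, a property the tests exploit. Paired
Cohen's d = mean(Δ)/SD(Δ) with bands negligible/small/moderate/large at
0.2/0.5/0.8, boundaries assigned to the higher band. Group contrasts by
speech label use the rank-sum test; label ~ age + sex uses logistic
regression with separation detection; tract-change vs
ventricular/tumor-volume associations use Pearson correlation (Spearman
available).

Per-segment change tests use the statistic z = mean(Δ)/SE per segment
with Benjamini–Hochberg correction within one family = one metric ×
tract × side (matching per-panel testing; 55 segments). Because the SE
is estimated from the same n subjects, the statistic is
Student-t(n−1)-distributed under the null; converting it with a normal
reference inflates the any-significant-segment rate several-fold at
n ≈ 30 (measured 12.4 % vs the nominal-plus-Monte-Carlo bound of 6.5 %
over 200 null cohorts). The default p-value therefore uses the t
reference — the statistic itself is unchanged — and
`reference = "normal"` reproduces the plain z-test for comparison.

## Simulation studies and problem sizes

The packaged studies run the full pipeline — phantom, tracking, gating,
tractometry, statistics — at sizes chosen for a single CPU:

* **Compression detection**: 100 cohort replicates × 30 subjects,
  affected tract only, macrostructural mode (no DWI simulation needed
  for volumes); detection = negative mixed-model timepoint effect at
  p < 0.05.
* **MD-window localization**: one 30-subject alteration cohort with
  full microstructure; the across-subject variance of ΔMD per segment
  is compared between the injected window (±1 segment) and the rest,
  and against the flat AF control.
* **Null calibration**: 200 cohort replicates × 20 subjects, affected
  tract only (the calibration property is per panel; with the t
  reference it holds at any cohort size).

Two computational shortcuts are exact by construction and are used by
the studies: (i) seeds are generated only where the peak amplitude
clears the FACT floor (background amplitude is exactly 0, so every
outside seed dies at length 0 — identical to whole-brain seeding);
(ii) a 15-mm minimum streamline length prunes fragments from seeds near
the support wall — every gated tract must span both endpoint ROIs and
is ≥ ~25 mm, so no tract metric can change. DWI can be simulated over
the whole brain mask or restricted to the tract support plus gray
matter (`simulateRegion = "tracts"`), the only voxels tract metrics
ever sample; studies use the restriction.

## Numerical choices and degenerate inputs

Spines are interpolated with `splinefun(method = "fmm")` (natural end
conditions bias end tangents by O(h)·curvature); coordinates use the
voxel-center convention world = (index + 0.5)·voxel with 0-based
indices and z = feet-head. Zero-SD difference vectors flag Cohen's d as
degenerate rather than dividing; all-zero paired differences make the
signed-rank p undefined (error); segments missing in more than half the
subjects are excluded from the z-tests and reported; singular
mixed-model fits are flagged and accompanied by a fallback paired
t-test; single-level sex drops the sex term from the logistic model.
Every random quantity derives from one integer seed (per-subject seeds
by fixed modular mixing, kept inside R's integer range), making every
cohort and study bit-reproducible.

## Known limitations

One peak per voxel means no crossing-fiber confounds — real d-DRTT
reconstruction fails disproportionately at the decussation, which the
phantom does not reproduce. Compression is modeled as radius scaling of
an otherwise fixed spine, not as a deformation field, so "brain shift"
effects on ROI alignment are absent. The left and right DRTT bundle
pairs share a dentate region and their support tubes can overlap there;
voxels are claimed by the first bundle listed. The SARA-based label is
a stand-in tied to the injected MD change, not a clinical model.
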