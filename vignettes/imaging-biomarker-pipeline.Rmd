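---
title: "Quantifying drug response in 3D bioprinted skin tumor models from bimodal confocal stacks"
author: "voxcyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug response in 3D bioprinted skin tumor models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcyte)
```

## The assay

`voxcyte` implements an imaging-biomarker assay for chemotherapeutic effect
in 3D bioprinted skin constructs (fibroblast-laden dermis, keratinocyte
epidermis) carrying cutaneous squamous-cell carcinoma (cSCC, A431) tumor
spheroids. Constructs are imaged non-destructively before and after a
treatment period by bimodal confocal microscopy: each fluorescence stack
(488 nm excitation for ZsGreen-labeled keratinocytes, 532 nm for
tdTomato-labeled cSCC) is acquired simultaneously with a reflectance (RCM)
stack of the same field. Only ~1% of keratinocytes carry the GFP label — a
spike-in design that keeps the green channel sparse and countable — while
every tumor cell is RFP-labeled.

Two imaging biomarkers are computed per analysis unit: the number of
segmented objects (a cell count) and their total fluorescence.
Keratinocyte biomarkers are computed over the whole construct; tumor
biomarkers per tumor region of interest (ROI). The treatment effect of a
unit is its post-treatment biomarker as a percent of the pre-treatment
value, and treated and control groups are compared with a pooled
two-sample t-test, Hedges' g, and an unbalanced two-way ANOVA with cell
type and treatment as crossed factors.

## Pipeline stages and their parameters

### Intensity normalization

Laser power and detector (photomultiplier) gain are constant between the
pre and post acquisitions of a sample but vary between acquisition
batches. Each fluorescence stack is therefore rescaled voxel-wise to a
reference setting pair before any cross-batch comparison:

\[
I' = I \cdot \frac{P_\mathrm{ref}}{P} \cdot
\left(\frac{G_\mathrm{ref}}{G}\right)^{\gamma}.
\]

The gain response is modeled as a power law with exponent $\gamma$
(default 1, i.e. linear). PMT gain curves are instrument-specific and no
calibration curve is available, so the exponent is an exposed parameter
rather than a buried assumption. The "standard image" is realized as the
reference (power, gain) pair in the configuration: for a linear model this
is mathematically identical to dividing by a standard image's scale.
Normalization precedes registration; the order is immaterial because the
transform is intensity-linear.

### Rigid registration

The two excitation channels are acquired sequentially, leaving a small
in-plane misalignment. Because each fluorescence stack has a simultaneous
reflectance companion, registration works on the z-sum projections of the
two reflectance stacks, which show the same label-free scene. The
estimator maximizes windowed normalized cross-correlation: a coarse grid
over rotation (default ±6° in 1° steps) with FFT-based translation
recovery and parabolic sub-pixel refinement per candidate, followed by a
0.1° local rotation refinement. The resulting transform is inverted and
applied slice-wise (bilinear interpolation, zero fill) to the moving
channel, so no intensity ever crosses z-slices — the projections are 2D,
so only in-plane misalignment is modeled. On noise-free phantoms the
recovery error is below 0.5 voxel and 0.5° for misalignments up to 8
voxels and 5° (acceptance suite); on the reduced test-scale phantoms the
rotation is resolvable to about 1°, which is why the unit test asserts the
looser bound.

### Segmentation

The published chain, reproduced by `segment()` with its defaults:

1. **Gaussian smoothing**, kernel size 8. The kernel size is interpreted
   as the truncated window width in voxels, giving taps over
   `±floor(8/2)` = ±4 voxels, with `sigma = kernel/4 = 2.0` voxels. The
   window-vs-sigma reading is ambiguous in common smoothing-call
   semantics, so both are independent parameters. Smoothing is 3D by
   default (`per_slice = TRUE` is available for strongly anisotropic
   stacks). Note that 2 voxels of axial sigma is ~6.2 µm at the default
   3.1 µm slice spacing — axial resolution after smoothing is about twice
   the lateral one, which drives the phantom geometry below.
2. **Otsu binarization** of the smoothed volume, on a 256-bin equal-width
   histogram spanning `[min, max]`. Bins are left-open, per-bin means are
   computed from the actual intensity sums (not bin midpoints), and the
   threshold is the upper edge of the selected bin; voxels strictly above
   it are foreground. With these choices the binned objective equals the
   exact between-class variance whenever distinct values fall in distinct
   bins, and the threshold matches an exhaustive intra-class-variance
   search (tested against that brute-force oracle). Ties select the
   lowest cut. Thresholding the *smoothed* stack follows from the stated
   stage order.
3. **Connected components** with 26-connectivity (faces, edges, corners);
   6 and 18 are available. Labels are assigned in scan order of each
   component's first voxel, so labeling is deterministic; the
   implementation is checked against a brute-force flood fill.
4. **Small-object removal**: components of 4 or fewer voxels are deleted
   (i.e. `min_object_voxels = 5`) and survivors relabeled consecutively.

One component counts as one cell; no watershed splitting is added, since
the published method counts segmented objects directly. Per-object
`total_fluorescence` is summed over the **pre-smoothing** normalized
intensities: smoothing is a detection aid and quantification should
reflect measured signal. (The original may have summed smoothed values;
for the ratio-based treatment effect the difference largely cancels.)

### Biomarkers, treatment effect and QC

Tumor ROIs are axis-aligned voxel boxes supplied with the manifest (the
phantom derives them from its spheroid geometry; for real data they are
drawn by the user — automatic tumor discovery is out of scope). Objects
are assigned to the ROI containing their centroid; objects outside every
ROI are reported in an `unassigned` bucket so per-ROI totals plus the
bucket always conserve the whole-stack total. Treatment effect is
`100 × post / pre` per unit and metric; units with a zero pre-treatment
baseline are excluded and logged.

Bleed-through of one fluorophore into the other detection channel makes
keratinocytes appear as tumor cells (or vice versa) and was an exclusion
criterion for whole acquisition batches in practice. `qc_bleedthrough()`
flags a sample when more than half (configurable) of its GFP objects have
an RFP object centroid within one cell radius (5 µm default, physical
distance); flagged samples are excluded from the group statistics.

### Group statistics

* **Pooled-variance two-sample t-test** (two-sided, df = n₁ + n₂ − 2),
  computable from raw effects or directly from published
  (mean, SD, n) summaries. The pooled form was chosen because
  recomputing the published tumor-cell comparison from its printed
  summaries reproduces the printed p-value under pooling.
* **Hedges' g** with the exact gamma-function small-sample correction
  \(J(\nu) = \Gamma(\nu/2) / (\sqrt{\nu/2}\, \Gamma((\nu-1)/2))\);
  the familiar `1 − 3/(4ν − 1)` approximation is available and agrees to
  1e-3 for ν ≥ 20. Sign convention: control minus treated, so a biomarker
  reduced by treatment gives positive g.
* **Two-way ANOVA for unbalanced designs** on the object-count effect,
  cell type × treatment with interaction, fitted with sum-to-zero
  contrasts and tested with Type III sums of squares (via `car::Anova`),
  which matches the default behavior of the n-way ANOVA tool used for the
  original analysis. On balanced designs the Type III sums of squares
  reduce to the classical decomposition; the test suite asserts this
  equivalence against a closed-form oracle at 1e-8.
* **Dose-response summary**: per-arm mean ± SD of the percent reduction
  `100 − percent_of_pre`, ordered control → 1× → 2×.

No multiple-testing correction is applied (none was in the source
analysis) and batch is not modeled as a random effect.

## The phantom generator

Raw data for this assay are hundreds of gigabytes of proprietary-format
stacks and are not publicly deposited, so the package ships a synthetic
phantom generator that every downstream stage is tested against.
`generate_phantom()` renders, per timepoint, four stacks (reflectance +
fluorescence × two channels) with full ground truth:

* **Geometry**: 28 × 240 × 240 voxels at 1.1 µm lateral pitch and 3.1 µm
  slice spacing (the acquisition geometry of the source study; spacing is
  valid in 1.5–5.3 µm). Five tumor spheroids of radius 32 µm with a dark
  necrotic core (fraction 0.5 of the radius) carry 10 tumor cells each on
  the viable shell; 2000 keratinocytes fill the rest of the construct, 1%
  of them GFP-labeled. Cell counts per spheroid, spheroid size and
  absolute intensities are not stated in the source and are free,
  documented parameters.
* **Cells** are isotropic Gaussian blobs in physical units
  (σ = cell radius / 2 = 2.5 µm), hence anisotropic in voxels, with
  ~10% log-normal brightness jitter fixed per cell across timepoints.
* **Resolvability by construction**: cell centers keep a minimum
  lateral-equivalent spacing of 15 µm, enforced in resolution-normalized
  coordinates — axial distances are down-weighted by the ratio of axial
  to lateral post-smoothing resolution (~2 at the default geometry). The
  threshold comes from a saddle-point argument: two equal blobs of
  combined post-smoothing sigma σ merge when the mid-point intensity
  2·exp(−d²/8σ²) exceeds the Otsu threshold (empirically ~0.3 of the
  peak above background), which is escaped for d ≳ 4.5σ ≈ 15 µm
  laterally. Phantom cells are therefore countable exactly in the
  noise-free case — by design, not by tuning. Real tumors violate this
  (touching cells merge into single objects), which is precisely why
  phantom tests validate the *pipeline's* correctness, not the biological
  accuracy of "one object = one cell" on dense tissue.
* **Spheroid placement** uses a jittered lateral grid: node spacing
  guarantees that the axis-aligned ROI boxes derived from the spheroids
  are pairwise disjoint, and mirrors spheroids pipetted onto the tissue
  surface. Pure sequential rejection sampling fails routinely at this
  packing density.
* **Reflectance texture**: a bright superficial band, a honeycomb middle
  band (dark nuclei on bright cytoplasm, the appearance of the stratum
  spinosum), and an anisotropically streaked fibrous lower band, blended
  along z. The scene is static across timepoints and shared between the
  channels, which is what makes projection-based registration meaningful.
* **Faults and nuisances**: per-channel/timepoint laser and gain factors
  (recorded in the manifest metadata, so normalization can undo them); a
  rigid misalignment of the RFP channel (default 1°, (2, −1.5) voxels);
  optional bleed-through adding a fraction of the RFP scene into the GFP
  channel (in the GFP frame, where the leak physically occurs); and
  sensor noise applied last as Poisson shot noise (photon scale 0.2
  photons per intensity unit) followed by Gaussian read noise (SD 8) with
  rounding and clamping to the 16-bit range.
* **Treatment** removes exactly `round(kill × n)` cells per population,
  drawn uniformly without replacement — removal rather than dimming, so
  the expected object count is unambiguous. Tumor kill is pooled across
  spheroids. Keratinocyte kill applies to the whole 2000-cell population,
  so the labeled 1% subset thins hypergeometrically, faithfully
  reproducing the spike-in design's extra sampling noise (and motivating
  the wider tolerance on keratinocyte recovery in the tests).
* The default per-arm kill fractions mirror the published outcomes:
  untreated controls lose ~13% of tumor objects over the imaging
  interval, the 1 µM arm ~52% (with ~11% keratinocyte loss), and the
  double-dose arm ~72%. The generator only removes cells, so it cannot
  reproduce the slight *growth* of control keratinocytes seen in the real
  data; control keratinocyte kill defaults to 0.

Every phantom is bit-reproducible from its seed and configuration, and
`PhantomGroundTruth` carries the true centers, transform, scale factors
and kill fractions for oracle-style assertions.

For statistical power questions a count-level companion,
`simulate_treatment_effects()`, thins per-sample counts binomially with
Beta-distributed per-sample kill heterogeneity (concentration 60, i.e.
~6% SD at a 50% kill). Rendering 4,000 full volumetric studies for a
power curve would be wasteful; the count-level model is the generative
model of the image phantom's counting process with the imaging layer
marginalized out.

## Numerical choices and degenerate inputs

* 1-based, inclusive (z, y, x) voxel coordinates throughout, the natural
  R convention; ROI boxes are inclusive on both ends.
* Stacks are stored as 16-bit unsigned integers on disk and processed in
  double precision; the TIFF round trip is lossless.
* Constant stacks: Otsu's threshold is undefined (error); `segment()`
  short-circuits constant volumes to an empty result.
* Zero pooled variance: t = 0, p = 1 when means are equal; an error
  otherwise. Zero pre-treatment baselines exclude the unit, with a log
  entry.
* Registration on a constant projection is a degenerate-input error.
* Problem sizes in the shipped tests: unit tests run a reduced phantom
  (18 × 112 × 112, 2 spheroids × 3 cells) chosen so that every stage's
  behavior — not its scale — is exercised; kill-fraction recovery and
  registration accuracy are asserted on the full-size default phantom
  over 20 seeds / 20 random transforms in the acceptance suite.

## Known limitations

* One connected component = one cell: touching cells merge; no watershed
  or learned instance segmentation.
* The phantom does not model optical PSF physics beyond Gaussian blur,
  tumor invasion dynamics, epidermal craters, keratinocyte
  differentiation, or proliferation (object counts can only decrease).
* Registration is rigid and in-plane only; no deformable or 3D rotational
  alignment, no flat-field correction.
* Tumor ROIs are user-supplied boxes; nothing discovers tumors
  automatically.
* Batch effects are handled by normalization and QC exclusion only, not
  by mixed-effects modeling.
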