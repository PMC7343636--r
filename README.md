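# voxcyte

Imaging biomarkers for drug response in 3D bioprinted skin tumor models.

`voxcyte` quantifies the effect of a chemotherapeutic (e.g. 5-fluorouracil)
on cutaneous squamous-cell carcinoma (cSCC) spheroids growing inside 3D
bioprinted skin constructs, from non-destructive bimodal confocal imaging:
each construct is imaged before and after treatment in two fluorescence
channels (tdT-RFP tumor cells, sparse Zs-GFP-labeled keratinocytes), each
acquired simultaneously with a reflectance (RCM) stack. It is aimed at
groups running image-based cytotoxicity assays on engineered tissue who
need a reproducible, testable pipeline from raw stacks to group statistics.

The pipeline:

1. **Normalization** of fluorescence for laser power and detector gain,
   `I' = I (P_ref/P) (G_ref/G)^γ`, so batches with different settings are
   comparable.
2. **Rigid registration** of the two channels from the z-sum projections of
   their reflectance stacks (windowed normalized cross-correlation,
   coarse-to-fine rotation search, FFT translation recovery), applied
   slice-wise.
3. **Segmentation**: 3D Gaussian smoothing (kernel size 8, σ = 2 voxels) →
   Otsu binarization (256-bin histogram) → connected components with
   26-connectivity → removal of objects of 4 or fewer voxels.
4. **Biomarkers** per unit (whole construct for keratinocytes, per tumor
   ROI for cSCC): object count and total fluorescence; **treatment effect**
   = post-treatment percent of the pre-treatment value, with bleed-through
   QC exclusion.
5. **Statistics**: pooled two-sample t-test, Hedges' g with the exact
   small-sample correction
   `g = J(ν) (m̄_control − m̄_treated)/s_pooled`,
   `J(ν) = Γ(ν/2)/(√(ν/2) Γ((ν−1)/2))`, unbalanced two-way ANOVA
   (cell type × treatment, Type III sums of squares), and a dose-response
   summary.

Because raw data for such assays are enormous and instrument-specific, the
package includes a **phantom generator** (`generate_phantom()`,
`simulate_dataset()`) that renders bimodal two-channel stacks of the skin
model — stratified reflectance texture, tumor spheroids with dark necrotic
cores, 1% GFP-labeled keratinocytes, laser/gain factors, inter-channel
misregistration, bleed-through faults, Poisson–Gaussian sensor noise — with
full ground truth, so the entire pipeline is testable end to end.

## Worked example

Simulate a small treated-vs-control study and run the full pipeline:

```r
library(voxcyte)

manifest <- simulate_dataset(
  "study_data",
  groups = c(control = 2, treated_1x = 2),
  seed = 7)                      # kills default to ~13% / ~52% tumor loss

res <- run_pipeline(pipeline_config(manifest, "study_out"))
res$group_stats[, c("channel", "metric", "control_mean", "treated_mean",
                    "p_value", "hedges_g")]
```

```
  channel             metric control_mean treated_mean      p_value hedges_g
1 GFP_488          n_objects       100.00       87.500 2.375071e-01 0.940316
2 GFP_488 total_fluorescence       100.07       87.517 2.442940e-01 0.920684
3 RFP_532          n_objects        88.00       48.000 1.600020e-07 3.529665
4 RFP_532 total_fluorescence        88.14       48.794 1.763022e-07 3.505957
```

Each row compares treatment effects (post as % of pre) between groups: the
simulated 1 µM arm retains ~48% of its tumor objects versus ~88% in
controls (per-tumor units, n = 10 per group here), while keratinocytes are
barely affected — the same selective-killing pattern the assay is designed
to detect. The ANOVA confirms the cell-type × treatment interaction:

```r
res$anova
#>                  term sum_of_squares df         F            p
#> 1           cell_type      2210.2083  1 19.800299 0.0002459525
#> 2           treatment      2296.8750  1 20.576708 0.0002011043
#> 3 cell_type:treatment       630.2083  1  5.645763 0.0276019224
#> 4          Residuals       2232.5000 20        NA           NA
```

Published summary tables can be re-analyzed directly, without raw values:

```r
control <- group_summary("control", n = 74, mean = 87, sd = 62)
treated <- group_summary("treated", n = 69, mean = 48, sd = 46)
two_sample_t(control, treated)
#> control vs treated: t(141) = 4.247, p = 3.91e-05, Hedges' g = 0.707
```

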