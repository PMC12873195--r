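# renalvol

Renal compartment volumetry and MRI method comparison on synthetic kidney
phantoms.

## What this is for

Renal sinus fat (RSF) — adipose tissue in the hilar cavity of the kidney —
is an emerging imaging biomarker for nephropathy risk, especially in type 2
diabetes. Quantifying it from segmented MRI volumes raises three recurring
methodological questions:

* how to score an automatic segmentation of renal parenchyma (RP) and RSF
  against a reference standard, and how well the derived volumes agree;
* whether the classical **single-slice** measurement at the renal pelvis is
  an adequate substitute for **whole-kidney** volumetry of the RSF-RP ratio
  (`ratio = V_RSF / V_RP`), given that sinus fat concentrates at the hilum;
* how much a **partial-coverage** protocol (thick axial slices with
  interslice gaps) biases RP and RSF volumes despite gap-compensating
  interpolation, and whether a linear adjustment
  `V_ref = a + b * V_gapped`, fitted per compartment, removes the bias.

`renalvol` implements this entire analysis pipeline for R users working with
labelled 3-D volumes (NIfTI in/out), together with a fully specified
synthetic kidney-phantom generator so that every stage — segmentation
metrics (DSC `= 2TP/(2TP+FP+FN)`, IoU, accuracy, sensitivity, precision,
specificity), Bland-Altman limits of agreement (`mean ± 1.96 SD` of paired
differences), ICC(A,1) from the two-way mean squares, Fisher-z intervals for
Pearson r, two-way ANOVA with Bonferroni post-hoc contrasts, shape-based
interpolation of every-4th-slice annotations, slab-sampling of gapped
acquisitions — runs and is tested end-to-end without any patient data.

## Worked example

```r
library(renalvol)

# A two-kidney phantom: superellipsoid RP bodies with hilum-anchored,
# lobulated sinus fat; 10% target fat burden, left kidney 30% fattier.
ph <- generate_phantom(phantom_params(seed = 7))
ph
#> kidney_phantom
#>   RP 268.8 cm^3, RSF 26.88 cm^3, RSF-RP ratio 0.100 (target 0.100)
#>   intensity channels: none

# Whole-kidney vs single-slice analysis
whole  <- compartment_volumes(ph$labels)
single <- single_slice_measures(ph$labels)
percent_difference(whole$rsf_rp_ratio, single$rsf_rp_ratio)
#> [1] -49.06895
```

The single-slice ratio (0.196, read at each kidney's largest cross-section)
nearly doubles the whole-kidney ratio (0.100) because fat concentrates at
the renal pelvis — a Δ% of −49 under the convention
`(whole − single)/single × 100`.

```r
# Score a degraded mask the way an automated segmentation would be scored
pred <- degrade_mask(ph$labels, boundary_shift_mm = 1,
                     label_noise_rate = 0.02, seed = 1)
label_metrics(pred, ph$labels, "RSF")
#> seg_metrics (label RSF): tp=5549 fp=934 fn=424 tn=238853
#>         dsc         iou    accuracy sensitivity   precision specificity
#>      0.8910      0.8034      0.9945      0.9290      0.8559      0.9961

# Simulate a 5 mm slice / 5 mm gap acquisition and re-estimate volumes
gapped <- gapped_volume_estimate(
  simulate_gapped_acquisition(ph$labels, protocol_config(5, 5)))
gapped
#>   rp_volume_cm3 rsf_volume_cm3 rsf_rp_ratio side method
#> 1      268.3238         24.795   0.09240703 both gapped
```

RP survives the gapped protocol almost unchanged (−0.2%) while RSF drops by
~8%: thin fat lobules filling less than 60% of a slab are diluted below
detectability. `fit_adjustment()` + `apply_adjustment()` learn and apply the
linear correction on paired cohorts.

Cohort-scale analyses are one call each: `run_experiment(config,
"agreement" | "slicewise" | "protocol")` generates a cohort (three glycaemic
groups, balanced sexes), runs the corresponding comparison and writes CSV
reports, JSON agreement summaries and a provenance record.

## Package tour

| Area | Functions |
| --- | --- |
| Containers | `label_volume()`, `intensity_volume()`, `compartment_mask()` |
| Phantoms | `phantom_params()`, `generate_phantom()`, `degrade_mask()`, `cohort_spec()`, `generate_cohort()` |
| Preprocessing | `preprocess_intensity()`, `foreground_gmm()`, `largest_components()`, `sparse_annotation()`, `interpolate_sparse_annotation()` |
| Metrics | `label_metrics()`, `metrics_report()` |
| Morphometry | `split_left_right()`, `compartment_volumes()`, `single_slice_measures()`, `percent_difference()` |
| Protocols | `protocol_config()`, `simulate_gapped_acquisition()`, `gapped_volume_estimate()`, `fit_adjustment()`, `apply_adjustment()` |
| Statistics | `bland_altman()`, `icc_absolute()`, `pearson_ci()`, `anova_two_way()`, `agreement_report()` |
| I/O & runs | `read_label_volume()`, `write_label_volume()`, `export_cohort()`, `run_config()`, `run_experiment()` |

The methods vignette (`vignettes/renal-compartment-methods.Rmd`) documents
the phantom model, every tunable parameter with its default and rationale,
the forward models of the protocol simulation, the statistical conventions,
and known limitations.
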