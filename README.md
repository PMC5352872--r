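# breastdwi

Quantifying how fat partial volume drives apparent diffusion
coefficient (ADC) measurements in the breast.

## The problem

Breast tissue is a mixture of fibroglandular tissue (FT) and fat with
very different water diffusivities. Any ADC region of interest (ROI)
that includes fat reports a blend, so women with low percent breast
density (PD = FT volume / breast volume × 100) appear to have low
"tissue" ADC purely because their ROIs contain more fat. `breastdwi`
implements the measurement chain needed to study this effect and a
synthetic ground-truth generator that makes every stage verifiable:

- **phantom / cohort** — axial breast MRI simulation: T1-weighted stack
  (1 × 1 × 4 mm), diffusion-weighted pair (b = 0, 1000 s/mm²) on a
  coarser misaligned grid (3.5 × 3.2 × 5 mm), speckled FT with exact
  voxel-count density, bias field, Rician noise, recorded truth;
- **normalize** — fuzzy C-means multiplicative bias-field correction
  with a low-pass accumulated gain;
- **segment** — chest landmarks, V-shape cut, slice propagation,
  exact 1-D k-means (k = 6, lower three clusters = FT), percent density;
- **register** — affine coregistration of the ADC map to T1 space by
  normalized mutual information, validity-aware resampling;
- **adc** — the four ROI strategies
  ADC_WB (whole breast) ≤ ADC_WF (whole-volume FT) ≤ ADC_SF
  (central-slice FT) ≤ ADC_SR (small homogeneous ROI, 10.7–66.1 mm²,
  possibly `not_measurable`), validity limits 100–3200 × 10⁻⁶ mm²/s,
  32-bin histograms, slice profiles;
- **stats** — Pearson correlations with PD, ICC(A,1) agreement, paired
  method comparisons, 10 %-density stratification, report bundle.

The statistic at the core is the contamination gradient: the mean ADC
of the four ROI strategies rises as fat is excluded, while the Pearson
correlation of each with PD falls — the apparent PD–ADC association is
a partial-volume artefact, recoverable in simulation because the truth
is known.

## Worked example

```r
library(breastdwi)

res <- run_pipeline(pipeline_config(
  cohort = cohort_spec(n_subjects = 6, seed = 5)
))
print(res)
#> <cohort_result> 6 subjects (6 analysed successfully)
#> <cohort_report>
#> Correlation of percent density with each ADC method:
#>  method         r n   p_value
#>  adc_wb 0.8404458 6 0.0361554
#>  adc_wf 0.6442185 6 0.1673532
#>  adc_sf 0.6571744 6 0.1561481
#>  adc_sr 0.5895412 6 0.2181383
#> Single-slice vs whole-volume FT ADC: Pearson r = 0.998, ICC = 0.970 (n = 6)
#> Stratification cutoff: 10% density

round(cbind(estimated = res$table$pd, true = res$table$true_pd), 2)
#>      estimated  true
#> [1,]      9.43  9.32
#> [2,]     24.22 24.14
#> [3,]     35.77 35.82
#> [4,]     12.00 11.87
#> [5,]      6.25  6.19
#> [6,]     24.67 24.71
```

Reading the output: estimated percent density tracks the ground truth
to a fraction of a percentage point; the whole-breast ADC correlates
strongly with density (r ≈ 0.84 even at n = 6) while the small-ROI ADC
— which excludes almost all fat — correlates weakly; and the
single-slice and whole-volume FT measurements agree nearly perfectly
with each other. Per-subject columns `adc_wb … adc_sr` carry the four
means (× 10⁻⁶ mm²/s), `sr_status` records subjects whose breasts were
too fatty or fragmented for a compliant small ROI.

Plots: `plot_pd_adc(res$table)`, `plot_density_curves(res$report)`,
`plot_slice_profile()`, and `autoplot()` on a phantom.

A thin command-line driver ships in `inst/cli/breastdwi.R`
(`simulate`, `run-all`, `report` subcommands; NIfTI + CSV + YAML
outputs).

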