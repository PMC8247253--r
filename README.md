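# fwlesion

Free-water imaging and apparent-fiber-density analysis of white-matter
lesions from single-shell diffusion MRI, with a fully synthetic test
cohort.

In cerebral small-vessel disease — and in CADASIL, its monogenic model —
white-matter hyperintensities (WMHs) are thought to arise where
extracellular fluid accumulates and damages the surrounding fiber
architecture. Testing that idea in vivo takes two quantities per voxel:
the **free-water fraction** *f* from the bi-tensor model

&nbsp;&nbsp;&nbsp;&nbsp;*A*(**g**, b) = *f* e^(−b·d_iso) + (1 − *f*) e^(−b·**g**ᵀT**g**),&nbsp;&nbsp;d_iso = 3.0×10⁻³ mm²/s,

and the **apparent fiber density** AFD = c₀₀·2√π, the spherical integral
of the white-matter fiber orientation distribution obtained by
single-shell 3-tissue constrained spherical deconvolution. `fwlesion`
implements both estimators, the free-water-corrected tensor metrics
(FAt, MDt, ADt, RDt), the lesion-mask machinery (NAWM construction,
free-water quartile subregions FWq1–FWq4, ICV-corrected volumes, lesion
probability maps), and the cohort statistics that connect them (paired
tests, one-way MANOVA with generalized η², Pearson/partial correlations
with Bonferroni adjustment, change-in-estimate logistic regression,
Cohen's kappa). A synthetic diffusion-MRI phantom with known ground
truth makes every stage testable without patient data.

The package is aimed at imaging-methods researchers who want a
transparent, tested reference implementation of this analysis chain —
not a replacement for production neuroimaging toolchains on real data
(preprocessing, registration and lesion segmentation are out of scope;
the package consumes preprocessed, co-registered volumes).

## Worked example

```r
library(fwlesion)

# a 6-subject synthetic cohort at SNR 40 on a 16 x 16 x 10 grid
report <- run_pipeline(phantom_config(n_subjects = 6, seed = 11))

report$qualitative
#> # A tibble: 4 × 3
#>   check                   value detail
#>   <chr>                   <dbl> <chr>
#> 1 fw_wmh_gt_nawm          0.357 sign test p = 0.0313
#> 2 afd_fwq1_gt_fwq4        1     fraction of subjects
#> 3 mdt_fwq4_gt_fwq1        1     fraction of subjects
#> 4 fw_afd_wmh_correlation -1.00  across-subject Pearson r

report$stats$paired[, c("metric", "estimate", "statistic", "p.value")]
#> # A tibble: 10 × 4
#>    metric   estimate statistic    p.value
#>    <chr>       <dbl>     <dbl>      <dbl>
#>  1 fw      0.357          19.9 0.00000594
#>  2 afd    -0.505         -20.4 0.00000518
#>  3 fat    -0.188         -13.1 0.0000463
#>  4 mdt     0.0000671      11.8 0.0000768
#>  5 adt    -0.000129      -10.8 0.000121
#>  6 rdt     0.000165       13.2 0.0000453
#>  7 fa     -0.311         -18.5 0.00000845
#>  8 md      0.000563       15.5 0.0000203
#>  9 ad      0.000340       15.1 0.0000230
#> 10 rd      0.000675       15.2 0.0000222
```

Reading the output: free water is higher inside lesions than in
normal-appearing white matter (+0.36), fiber density is lower (−0.50),
and fiber density falls monotonically from the lowest to the highest
free-water quartile while tissue mean diffusivity rises — the
FW–degeneration association the analysis is built to detect. Note the
signature split between ADt (down in lesions) and conventional AD (up):
removing the free-water compartment flips the apparent direction of the
axial diffusivity change.

Individual stages are ordinary functions — `simulate_cohort()`,
`fit_dti()`, `fit_freewater()`, `estimate_responses()`,
`fit_ss3t_csd()`, `afd_map()`, `make_nawm()`, `split_fw_quartiles()`,
`build_lpm()`, `logistic_cie()`, … — and the statistical results carry
`tidy()`/`glance()` methods and `autoplot()`s. A thin command-line
front end lives at `inst/cli/fwlesion.R`
(`simulate | fit | analyze | run-all | validate`).

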