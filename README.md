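# glymphomics

Tools for studying brain glymphatic function — the perivascular
waste-clearance system — alongside gut-microbiome and plasma-metabolome
data, in cohorts such as older adults with white matter hyperintensities
(WMH) stratified by cognitive status. The package implements the full
analytic chain from derived inputs to a mediation model of the
microbiota → metabolites → glymphatic function → cognition pathway:

* **Five MRI glymphatic markers** computed from derived volumes and
  series:
  * the DTI-ALPS index
    `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`
    from directional diffusivity maps with 5-mm spherical ROIs in the
    superior corona radiata and superior longitudinal fasciculus
    (`compute_alps()`);
  * the single-shell two-compartment free-water fraction
    `S = S0 [ f e^(-b d_iso) + (1-f) e^(-b gᵀDg) ]` with
    `d_iso = 3.0e-3 mm²/s`, and its white-matter mean excluding
    perivascular spaces (`fit_free_water()`, `mean_fw_wm()`);
  * Frangi multiscale vesselness segmentation of perivascular spaces and
    the basal-ganglia PVS volume fraction (`frangi_vesselness()`,
    `segment_pvs()`);
  * the choroid-plexus volume fraction (`cpv_fraction()`);
  * BOLD–CSF coupling: the cross-correlation of the global BOLD and CSF
    inflow signals over ±10 s lags, with the group-level negative-peak
    lag convention (`bold_csf_ccf()`, `gbold_csf_coupling()`,
    `network_coupling()`).
* **Omics group statistics**: Bray–Curtis / PCoA ordination, seeded
  PERMANOVA, covariate-adjusted Kruskal–Wallis with Dunn–Bonferroni post
  hoc tests, one-way ANOVA reconstructed exactly from printed group
  summaries, Pearson chi-square, and an auditable metabolite QC chain
  (QC/blank ≥ 3, RSD ≤ 30%, prevalence ≥ 80%, 1/5-minimum imputation, QC
  normalization, glog, z-score).
* **Serial two-mediator mediation** with the pathway decomposition
  `c = c' + a1·b1 + a2·b2 + a1·d·b2` and percentile bootstrap confidence
  intervals (`serial_mediation()`, `mediation_grid()`,
  `partial_spearman()`).
* **A synthetic-data module** (`gen_mediation_cohort()`,
  `gen_group_omics()`, `gen_dwi_phantom()`, `gen_coupling_series()`,
  `gen_tube_phantom()`) that generates every input with known ground
  truth, so the whole chain is testable without any download.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, and `autoplot()` methods for
ordinations, mediation fits, and cross-correlation functions.

## Worked example

Reconstruct a published three-group cohort table from its printed
summaries, then fit a serial mediation model on a synthetic cohort with
planted paths:

```r
library(glymphomics)

head(demographics_table_stats(), 7)
#> # A tibble: 7 × 4
#>   variable     test       statistic   p_value
#>   <chr>        <chr>          <dbl>     <dbl>
#> 1 female       chi-square      3.36 0.186
#> 2 hypertension chi-square     20.4  0.0000380
#> 3 diabetes     chi-square      4.82 0.0897
#> 4 dyslipidemia chi-square      1.10 0.576
#> 5 smoking      chi-square      1.66 0.435
#> 6 age          anova           2.88 0.0593
#> 7 education    anova           1.12 0.330
```

Only hypertension differs across the groups (χ² = 20.4, p < 0.001): the
WMH groups are more hypertensive than controls, while age, sex and
education are comparable — the chi-square and F statistics are exact
functions of the printed counts and of the printed means/SDs/ns.

```r
truth <- cohort_truth(c(HC = 56, `WMH-NC` = 40, `WMH-CI` = 49),
  mediation_paths = c(a1 = 0.5, a2 = 0.3, d = 0.4, b1 = 0.3, b2 = 0.4, c_prime = 0.2),
  seed = 42)
cohort <- gen_mediation_cohort(truth, n = 145)   # x -> m1 -> m2 -> y + covariates
fit <- serial_mediation(cohort, "x", "m1", "m2", "y",
  covariates = c("c1", "c2", "c3", "c4"), n_boot = 5000, seed = 1)
fit
#> <serial_mediation> n = 145, 4 covariates, 5000 bootstrap draws (seed 1)
#>   effect            pathway estimate conf_low conf_high significant
#>        c              total  0.46957  0.24098    0.6721        TRUE
#>  c_prime             direct  0.15590 -0.04097    0.3348       FALSE
#>      ie1       x -> m1 -> y  0.17730  0.08416    0.2898        TRUE
#>      ie2       x -> m2 -> y  0.04745 -0.02526    0.1404       FALSE
#>      ie3 x -> m1 -> m2 -> y  0.08891  0.04030    0.1515        TRUE
```

At the study's sample size the fit recovers the planted structure: the
indirect paths through the first mediator (`ie1`, a metabolite in the
motivating design) and through the serial chain (`ie3`,
metabolite → glymphatic marker → cognition) have 95% bootstrap intervals
excluding zero, and the decomposition identity holds to machine
precision (`glance(fit)$identity_gap` ≈ 6e-17). `autoplot(fit)` draws the
forest plot.

`run_pipeline(run_config("out", seed = 1))` chains the synthetic
generators, markers, group statistics, and mediation into one
reproducible output directory; rerunning with the same seed reproduces
every data file byte for byte.

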