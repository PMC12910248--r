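---
title: "Models and methods behind glymphomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glymphomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphomics)
```

# Scope

glymphomics implements the analytic chain that links gut-microbiome and
plasma-metabolome tables to MRI-derived markers of brain glymphatic
(perivascular waste-clearance) function and to cognition: five imaging
markers computed from derived volumes and time series, group-level omics
statistics, and a serial two-mediator bootstrap mediation model. A
synthetic-data module generates every input with known ground truth, so
each stage is testable end to end without any external download. The
package consumes *derived* data — directional diffusivity maps, tissue and
ROI label volumes, preprocessed BOLD series, count and intensity tables —
and deliberately implements no registration, denoising, segmentation of
anatomy, or sequencing upstream.

# The five glymphatic markers

## ALPS index

The index of diffusivity along the perivascular spaces compares x-axis
diffusivity in projection- and association-fibre regions at the level of
the lateral-ventricle body with the diffusivities perpendicular to both
tracts:

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx,proj},\; D_{xx,assoc})}
                        {\mathrm{mean}(D_{yy,proj},\; D_{zz,assoc})}.$$

`compute_alps()` evaluates the four means inside 5-mm spheres centred in
the superior corona radiata (projection) and superior longitudinal
fasciculus (association) of each hemisphere, forms the per-hemisphere
ratio, and averages left and right. The default centres — left SCR
(116, 110, 99), left SLF (128, 110, 99), right SCR (64, 110, 99), right
SLF (51, 110, 99) — are interpreted as **0-based voxel indices** in the
JHU-ICBM FA 1-mm template grid; the convention is declared in the
`alps_rois()` object and the centres are fully overridable, since the
index origin is not standardised across toolchains. Spheres are
rasterised as voxels whose centres lie within `diameter/2` (world mm) of
the centre voxel's world position. No correction for white-matter
asymmetry is applied. The ratio is scale-free: multiplying all three maps
by a positive constant leaves it unchanged, which the test suite asserts.

## Single-shell free-water fraction

Each voxel's diffusion signal is modelled as a two-compartment mixture of
an isotropic free-water pool with fixed diffusivity
$d_{iso} = 3.0\times10^{-3}\,\mathrm{mm^2/s}$ (water at body temperature)
and a tissue tensor $D$:

$$S(b, g) = S_0\left[f e^{-b d_{iso}} + (1-f)\,e^{-b\, g^\top D g}\right].$$

Two numerical choices matter:

* **Shared amplitude.** $S_0$ is estimated from the $b=0$ volumes and is
  shared by both compartments. If the tissue amplitude is left free the
  model becomes a sum of two unconstrained exponential families and $f$
  is unidentifiable on a single shell; tying the tissue $b=0$ amplitude
  to $(1-f)S_0$ is what identifies $f$ at all.
* **Profile optimisation.** For a candidate $f$, the tensor given $f$ is
  a weighted log-linear fit (weights $\propto$ signal$^2$, the
  delta-method weighting); the residual is evaluated in signal space.
  `fit_free_water()` scans a 21-point grid over $f$ (vectorised across
  voxels), then refines $f$ by bounded one-dimensional optimisation
  around the best grid point. Tensor eigenvalues are clipped to $\ge 0$;
  voxels with $S_0 \le 0$ are flagged not converged and excluded from
  summaries.

On noiseless phantoms this recovers the planted field to $<10^{-6}$ and
agrees with an exhaustive $10^{-3}$-resolution grid search. At realistic
noise, however, the single-shell problem is *weakly identified per voxel*:
a numerical Cramér–Rao computation for the 64-direction $b=1000$ scheme at
SNR 40 gives $\sigma_f \approx 0.8$–$1.5$ depending on the tissue tensor —
larger than the whole $[0,1]$ range. No per-voxel estimator can beat this;
published single-shell implementations rely on strong spatial
regularisation for the same reason. `regularize = TRUE` therefore (i)
estimates the noise level from the $b=0$ repeats, (ii) applies the Rician
second-moment correction $\hat S^2 = m^2 - 2\hat\sigma^2$ (exact in
expectation), and (iii) pools the corrected squared signal spatially —
with a Gaussian of `reg_sigma_vox` voxels, or over the whole mask by
default, which is appropriate when the mask delimits a homogeneous region
such as a white-matter ROI. The marker used downstream, FW-WM, is exactly
such a region mean: `mean_fw_wm()` averages the fitted map over the
white-matter mask minus the perivascular-space mask.

Validation phantoms use a corpus-callosum-like tissue tensor
$\mathrm{diag}(1.8, 0.25, 0.25)\times10^{-3}\,\mathrm{mm^2/s}$
(FA $\approx 0.89$, MD $\approx 0.77\times10^{-3}$): a realistic tensor in
the regime where the single-shell model is best conditioned, which is the
appropriate setting for testing the fitter rather than the model's known
degeneracy at low anisotropy.

## Perivascular-space segmentation

`frangi_vesselness()` is a multiscale Hessian vesselness filter for
bright tubes on a dark background. Per scale $s$ the volume is convolved
with sampled Gaussian-derivative kernels (moment-corrected so constants
and linear ramps respond exactly zero under replicate-edge padding),
second derivatives are scale-normalised by $s^2$, and the symmetric
$3\times3$ eigenvalues are obtained by the closed-form trigonometric
method, sorted by magnitude $|\lambda_1|\le|\lambda_2|\le|\lambda_3|$.
The response combines plate rejection $R_A=|\lambda_2|/|\lambda_3|$, blob
rejection $R_B=|\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$, and
structureness $S$ (Frobenius norm), and is zero wherever
$\lambda_2>0$ or $\lambda_3>0$:

$$V = \left(1-e^{-R_A^2/2\alpha^2}\right) e^{-R_B^2/2\beta^2}
      \left(1-e^{-S^2/2c^2}\right),$$

with the recommended defaults $\alpha=\beta=0.5$ and, for `c = "auto"`,
half the per-scale maximum Frobenius norm. Scales default to 0.1–5
voxels; scales are interpreted in voxel units and a warning is issued for
anisotropic voxels. `segment_pvs()` thresholds the vesselness map
(default cutoff $2\times10^{-5}$, the published clinical operating point
for denoised T1 intensities — phantom tests with unit-contrast tubes use
a scale-appropriate cutoff instead, since the vesselness magnitude
depends on the intensity scaling), intersects it with the basal-ganglia
labels, and reports the volume fraction PVSVF-BG = segmented volume /
intracranial volume. `cpv_fraction()` is the analogous choroid-plexus
volume fraction.

## BOLD–CSF coupling

`bold_csf_ccf()` computes the Pearson correlation of overlapping,
lag-shifted segments of the global grey-matter BOLD signal and the CSF
inflow signal at every multiple of TR within ±10 s (no sub-sample
interpolation; minimum overlap 30 samples, shorter overlaps are missing).
Positive lags mean CSF follows gBOLD. The marker convention is
group-level: `gbold_csf_coupling()` averages the cross-correlation
functions over subjects, fixes the lag of the most negative mean
correlation (ties broken toward smaller |lag|, then positive), and reads
each subject's strength at that fixed lag. `neg_derivative_check()`
verifies the physiological signature that CSF inflow matches rectified
BOLD *decreases* ($\max(0, -\mathrm{d}BOLD/\mathrm{d}t)$ correlates
positively near zero lag). `network_coupling()` repeats the per-voxel
negative-peak rule and averages strengths within arbitrary network
labels.

# Omics statistics

* **Ordination and PERMANOVA.** `bray_curtis()` computes
  $d(i,j)=\sum_k|x_{ik}-x_{jk}| / \sum_k(x_{ik}+x_{jk})$ (via vegan);
  `pcoa()` performs classical scaling and reports *all* eigenvalues,
  including negative ones, without correction — Bray–Curtis is
  non-Euclidean and correcting would change the inertia decomposition;
  axis signs are fixed by making each axis's largest-magnitude
  coordinate positive. `permanova()` (backed by `vegan::adonis2`, seeded
  locally) returns the pseudo-F and the permutation p-value
  $(1+\#\{F^{perm}\ge F\})/(1+n_{perm})$; 1000 permutations is the
  working convention. The test suite checks it against a hand-written
  exhaustive-enumeration oracle on small two-group instances and
  verifies 5% type-I error by simulation.
* **Covariate-adjusted rank tests.** The adjustment mechanism for
  Kruskal–Wallis is deliberately simple and declared in the output: the
  response is residualised on the covariates by OLS, and the classical
  tie-corrected H is computed on the residual ranks. Alternatives
  (stratification, rank ANCOVA) exist; residualisation preserves the
  nominal type-I error under covariate-driven nulls (verified at 500
  simulations) and reduces exactly to classical Kruskal–Wallis with no
  covariates. `dunn_posthoc()` provides the pairwise z-tests on pooled
  mid-ranks with tie correction and Bonferroni factor equal to the
  number of pairs (3 for three groups).
* **Summary-statistic ANOVA and chi-square.** `oneway_anova_summary()`
  reconstructs the one-way F exactly from per-group means, SDs and
  sizes, so a published demographics table can be re-derived without
  subject data; the raw-data overload agrees to machine precision.
  `group_chisq()` is Pearson's chi-square *without* continuity
  correction — the convention that reproduces printed cohort-table
  values. `cohort_summaries()` ships the published summaries of a
  three-group WMH cohort (healthy controls, WMH with normal cognition,
  WMH with cognitive impairment) as plain-text inputs for exactly this
  reconstruction.
* **Metabolite QC chain.** `metabolite_qc()` applies, in order:
  QC/blank mean-ratio filter (< 3 removed), QC relative-standard-
  deviation filter (> 30% removed), subject prevalence filter (< 80%
  nonzero removed), imputation of remaining zeros by 1/5 of the
  feature's minimum positive value, per-feature division by the QC
  median (no injection-order correction, as injection order is not part
  of the input), the generalised log
  $g(x)=\log_2\!\big((x+\sqrt{x^2+\lambda^2})/2\big)$ with $\lambda$ the
  feature's minimum positive value, and per-feature z-scoring over
  subjects. Each removal is attributed to exactly one rule in an audit
  table; features that survive filtering but cannot be scaled (no
  positive values, zero variance) are removed with their own audit
  entries. The chain records its completed stages, making it idempotent.

# Serial two-mediator mediation

`serial_mediation()` fits, by OLS with intercepts and covariates,

$$M_1 \sim X, \qquad M_2 \sim X + M_1, \qquad Y \sim X + M_1 + M_2,
  \qquad Y \sim X,$$

yielding paths $a_1, a_2, d, b_1, b_2, c'$ and the total effect $c$. With
identical covariate sets the decomposition

$$c = c' + a_1 b_1 + a_2 b_2 + a_1 d b_2$$

is an algebraic identity of least squares; the total-effect model is
nevertheless fitted separately and the identity is used as a runtime
self-check (reported as `identity_gap`, required $<10^{-10}$ in the
tests). Confidence intervals are nonparametric case-resampling bootstrap
percentile intervals — Efron's order-statistic convention — with a fixed
seed (5000 draws by convention); an effect is significant when its
interval excludes zero. Draws with singular designs are discarded,
redrawn and counted, with a warning above 1% discards. Analysis is
complete-case; binary covariates are coded 0/1. Bias-corrected intervals
are not the default because the percentile variant is the declared
convention; the bootstrap draws are returned so other intervals can be
formed. Bootstrap refits solve the normal equations on the resampled Gram
matrix (one cross-product per draw), which makes 500-simulation coverage
studies practical; point estimates and standard errors use QR.

Two properties of the *method*, not the implementation, shape the
validation design. First, a fully noise-free generator is degenerate:
with zero residual SDs, $M_1$ is an exact linear function of $X$ and the
downstream designs are exactly singular, so exact-recovery tests plant
noise on the mediator equations and zero noise on $Y$, where $b_1, b_2,
c'$ are recovered exactly. Second, the percentile bootstrap's true
coverage for a product of coefficients is regime-dependent: near 100% at
the complete null (both factors zero) and around 92% when the
complementary path is strong. The null-calibration study therefore
detaches $X$ ($a_1=a_2=c'=0$) while keeping moderate mediator-chain
coefficients ($d=0.3$, $b_1=0.3$, $b_2=0.45$), the regime in which the
method is near-nominal; measured coverage is 93–97% over 500 simulated
cohorts of $n=145$ with 1000 bootstrap draws.

`partial_spearman()` mid-ranks both variables, residualises the ranks on
the covariates, and correlates the residuals with a t-approximation on
$n-2-q$ degrees of freedom. `mediation_grid()` batches
`serial_mediation()` over candidate (X, M1, M2, Y) combinations with
deterministic child seeds and no multiplicity correction across models.

# The synthetic-data module

The generators define the conditions under which everything above is
validated:

* `gen_mediation_cohort()` draws the linear recursive system with
  standard-normal X, Gaussian residuals, and covariates (one binary, the
  rest continuous) whose coefficients come from the seeded stream.
* `gen_group_omics()` draws taxa from a log-normal compositional model
  closed to sum one — planted group effects are exact log-scale shifts
  applied before closure, which is why log-normal-plus-closure was chosen
  over a Dirichlet — with between-sample log-SD 0.5, a realistic value
  for genus-level abundances at which a planted two-fold shift is
  detectable at n = 40/group. Metabolite tables add pooled-QC replicates
  with controllable RSD, blanks with controllable background ratio, and
  controllable missingness so every QC rule has passing and failing
  features.
* `gen_dwi_phantom()` evaluates the two-compartment signal equation
  exactly and corrupts it with Rician noise (magnitude of
  complex-Gaussian-perturbed signal) at a stated SNR — the noise model of
  magnitude MRI — or not at all.
* `gen_coupling_series()` band-limits Gaussian noise to 0.01–0.1 Hz at
  the stated TR (the resting-state frequency band), shifts and negates it
  for the CSF channel, and calibrates additive independent noise so the
  population cross-correlation peak magnitude equals the requested
  amplitude. Lags are sample-resolution; off-grid requests are rounded
  and reported. The defaults (TR 2 s, 175 volumes, lag +4 s, amplitude
  0.8) mirror a typical resting-state acquisition.
* `gen_tube_phantom()` places non-overlapping bright cylinders at random
  orientations with an exact truth mask; placement failures after bounded
  retries raise an error rather than silently overlapping.

All generators take explicit seeds, restore the caller's RNG state, and
return the truth object alongside the data. What the generators do *not*
emulate: read-level sequencing noise, mass-spectral artefacts, scanner
k-space artefacts, motion, or spatial misregistration — so green tests
demonstrate correctness of the computations on data that satisfy the
models' assumptions, not robustness to the full messiness of acquired
data.

# Reproducibility conventions

Seeds are hierarchical: `derive_seed(master, key...)` hashes the master
seed with a stage or combination key into a 31-bit child seed, so adding
one analysis never perturbs another's stream. `run_pipeline()` chains
synth → markers → stats → mediation, writes tab-separated outputs with
`NA` for missing values plus the resolved configuration, and is
byte-identical under a fixed seed (imaging outputs are written as
uncompressed NIfTI for this reason; gzip embeds timestamps). `--resume`
regenerates only stages whose outputs are missing. Problem sizes used in
the validation suite — 20³ phantom grids, 100-seed recovery studies,
500-seed calibration studies with 1000 bootstrap draws, 199-permutation
PERMANOVA calibration — were chosen as the smallest sizes at which the
Monte-Carlo error is well below the tolerances being asserted.

# Known limitations

* The single-shell free-water fit without regularisation is only suitable
  for noiseless or very-high-SNR data; this is intrinsic to the model.
* Vesselness thresholds are intensity-scale-dependent; the published
  cutoff applies to the preprocessing it was optimised for.
* The covariate adjustment for rank tests and the QC normalisation rule
  are declared conventions among several defensible choices.
* Mediation results are associational; no sensitivity analysis for
  unmeasured confounding is provided, and no multiplicity correction is
  applied across mediation models.
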