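---
title: "Free water, fiber density and white-matter lesions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free water, fiber density and white-matter lesions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fwlesion` studies the relationship between extracellular free water (FW)
and white-matter fiber integrity inside white-matter hyperintensities
(WMHs), the lesions that dominate cerebral small-vessel disease. This
vignette is the package's own account of the models it implements, the
parameters that matter, and the design decisions taken where more than one
reasonable choice existed.

## The signal model

All voxel-level machinery rests on one forward model for single-shell
diffusion MRI (one b = 0 volume plus one shell, b = 1000 s/mm2 by
default). On attenuations $A = S/S_0$:

$$A(\mathbf{g}, b) \;=\; f\, e^{-b d_{iso}} \;+\; (1-f) \sum_k w_k\,
e^{-b\, \mathbf{g}^\top T_k \mathbf{g}}$$

where $f \in [0,1]$ is the free-water fraction, $d_{iso} = 3.0\times
10^{-3}$ mm$^2$/s is the diffusivity of free water at body temperature,
and $T_k$ are tissue compartment tensors ($K = 1$ except in
crossing-fiber voxels). Magnitude noise is Rician:
$\tilde S = \sqrt{(S + n_1)^2 + n_2^2}$ with $n_i \sim N(0, \sigma^2)$
and $\sigma = S_0/\mathrm{SNR}$.

## Conventional and free-water-corrected tensor fits

`fit_dti()` solves the log-linear system $\log S = \log S_0 - b\,
\mathbf{g}^\top D \mathbf{g}$ by least squares and derives FA, MD, AD, RD
from eigenvalues clipped below at zero. On noiseless single-tensor input
this inversion is exact (tested to 1e-8 relative error).

`fit_freewater()` estimates $(f, T)$ per voxel with $f$ box-constrained
to $[0,1]$ and tissue eigenvalues constrained to $[0.1, 2.5] \times
10^{-3}$ mm$^2$/s. The estimator profiles the signal-space residual over
$f$: at each candidate fraction the tissue attenuation is recovered
algebraically, the tensor solved by weighted log-linear least squares
(weights $A_t^2$), eigenvalues clipped into the band, and the residual
evaluated against the measured attenuations. A coarse grid over $f$
(seeded with a moment-based start
$f_0 = \mathrm{clip}\{(e^{-b d_t} - \bar A)/(e^{-b d_t} - e^{-b d_{iso}}),
0.05, 0.95\}$ with $d_t = 0.7\times10^{-3}$ mm$^2$/s) is refined by
golden-section search.

**Why a prior is unavoidable.** With a single shell, the decomposition is
only weakly identified: the residual profile is nearly flat below the true
fraction, because a smaller $f$ can be compensated by a faster, more
isotropic tissue tensor. A plain per-voxel nonlinear fit therefore wanders
freely at realistic SNR (errors of 0.2-0.3 in the fraction). Published
free-water estimators resolve this with spatial regularization; a
per-voxel estimator needs a tissue prior instead. `fit_freewater()` adds
one extra least-squares row pulling the tissue mean diffusivity toward
$d_t$, weighted by the voxel's estimated noise variance (taken from the
minimum unpenalized residual). This is the MAP scaling of a Gaussian
prior: on noiseless data the weight vanishes and the fit inverts the model
exactly; at SNR 40 it pins the flat direction and brings the mean absolute
fraction error below 0.05 (tested). The prior scale `md_prior_sd`
defaults to $0.25\times10^{-3}$ mm$^2$/s, a generous band around typical
parenchymal diffusivities. For isotropic tissue the decomposition is
fundamentally non-identifiable; the fit settles at the prior-regularized
solution and flags nothing, which is intended behavior.

Volume fits optionally apply one pass of mask-aware 6-neighbor smoothing
to the fraction field (`smooth_weight = 0.3`), standing in for the spatial
regularization of the published estimators; the tissue tensor is re-solved
at the smoothed fraction. Tissue metrics FAt/MDt/ADt/RDt come from the
tissue tensor through exactly the same eigenvalue step as `fit_dti()`.

## Fiber orientation distributions and apparent fiber density

`estimate_responses()` derives the three tissue response functions from
the data: the WM response is the average zonal spherical-harmonic profile
of high-FA voxels after rotating each voxel's principal direction to the
pole (default threshold 0.65 - slightly below the textbook 0.7, because
even 10% background free water depresses raw-DTI FA of genuine
single-fiber voxels); GM and CSF responses are mean attenuations over
their masks. `average_responses()` averages coefficient-wise across
subjects, and `fit_ss3t_csd()` deconvolves each voxel against the
group-average responses.

The deconvolution solves, per voxel, for the even-order spherical-harmonic
coefficients of the WM fiber orientation distribution (FOD) plus
nonnegative GM and CSF scalars, minimizing the squared misfit to the b0 +
shell attenuations subject to FOD nonnegativity on a 150-point Fibonacci
hemisphere. Two numerical facts shaped the implementation:

* With one b0 and one shell, the three isotropic quantities (the FOD's
  $\ell = 0$ term, GM, CSF) span only two observable dimensions - the
  single-shell three-tissue degeneracy. A tiny ridge makes the quadratic
  program strictly convex, and the nonnegativity constraints select the
  physically meaningful allocation wherever one exists (a pure-CSF voxel,
  for instance, has a unique feasible solution).
* Iteratively reweighted constraint schemes either oscillated or, under
  weight escalation, slid isotropic mass into the wrong compartment along
  the degenerate direction. The constraints are therefore enforced
  exactly: the QP is solved through its dual, a nonnegative least-squares
  problem handled by a Lawson-Hanson solver with ridge-protected passive
  solves. Residual constraint violations are below $10^{-4}$ of the peak
  FOD amplitude by construction (tested).

`lmax` defaults to the largest even degree the measurement count supports
(8 at most); with 31 measurements this is 6, announced with a warning.
Apparent fiber density is the spherical surface integral of the FOD,
$\mathrm{AFD} = c_{00}\, 2\sqrt{\pi}$ in the orthonormal real basis,
checked against Gauss-Legendre product quadrature. Global intensity
normalization rescales each subject so the median WM total tissue signal
(FOD integral + GM + CSF) equals one; no spatially varying bias field is
modeled because the phantom does not simulate one, and untestable code is
worse than a documented absence.

## Lesion masks, quartile subregions, probability maps

Normal-appearing white matter (NAWM) is WM minus WMH, eroded twice with
the 6-connected structuring element - the most conservative reading of
"two voxels in three dimensions" - to keep partial-volume voxels out.
The WMH mask is split at the 25th/50th/75th FW percentiles into FWq1-FWq4;
intervals are upper-closed so boundary ties fall into the lower quartile,
and a degenerate all-equal map lands entirely in FWq1. Regional means,
ICV-corrected volumes (voxel volume times count over intracranial volume)
and lesion probability maps (voxelwise lesion frequency across subjects,
with the peak's 26-connected plateau cluster volume) complete the module.

## Cohort statistics

The statistics layer is deliberately classical: paired t tests for WMH vs
NAWM; one-way MANOVA (Pillai trace) across the four FW-quartile
subregions with per-metric F, generalized eta squared
$\eta^2_g = SS_b/(SS_b + SS_w)$ (identical to classical eta squared in
this one-way between-group design) and all pairwise contrasts
Bonferroni-adjusted; Pearson and partial correlations (residual-on-
covariates method, degrees of freedom reduced accordingly) with a
Bonferroni family spanning the requested pairs; logistic regression with
change-in-estimate confounder selection (a candidate is retained when
adding it moves the exposure odds ratio by at least 10% relative to the
current working model; a `base = "crude"` flag switches the comparison
base); and Cohen's kappa with its large-sample standard error.

Two caveats are worth stating. First, treating the four subregions as
independent groups ignores that they are repeated within subject; this is
the analysis as classically reported in this literature, and a
repeated-measures univariate variant (`repeated = TRUE`) is exposed for
users who prefer it. Second, MDt is exactly $(ADt + 2\,RDt)/3$, so a
multivariate statistic over all five FW-corrected metrics is singular by
construction; the pipeline's default multivariate set is therefore
{AFD, FAt, MDt, RDt}, with ADt retained in the univariate comparisons and
correlations. `oneway_manova()` refuses singular metric sets rather than
silently dropping columns.

## The synthetic cohort

`simulate_cohort()` generates the study conditions every test runs under:
20 subjects on a shared 16 x 16 x 10 grid at 1 mm$^3$ (a stand-in for
template registration; real-data use requires pre-registered masks), 30
gradient directions plus one b0 at b = 1000 s/mm$^2$, SNR 40. A CSF slab
occupies one face of the grid (the "ventricle"), a GM slab the opposite
face, and a WM slab fills the interior with fibers along one axis; 30% of
WM voxels carry a second orthogonal fiber population, the case that
motivates spherical deconvolution over the tensor model. Spherical
lesions seed near the ventricular face; within lesions the ground-truth
free water rises linearly toward the ventricle from 0.1 to 0.7 (with
seeded jitter of SD 0.02 so quartile splits see distinct values), and
fiber density follows `density = 1 - 0.8 * FW`, clipped at zero.

The tissue tensor of a WM voxel is the density-weighted mixture
$T = \rho\,T_{fiber} + (1-\rho)\, d_{deg} I$ with fiber eigenvalues
$(1.7, 0.3, 0.3)\times10^{-3}$ mm$^2$/s and degraded-tissue diffusivity
$d_{deg} = 1.2\times10^{-3}$ mm$^2$/s. The mixture encodes the
histology-motivated reading of fiber loss - fewer axons hinder water
less - so toward high-FW lesion cores MDt and RDt rise while FAt and ADt
fall, and conventional AD rises while ADt falls (the free-water
contamination pulling AD up is removed in the tissue compartment). A pure
eigenvalue scaling by density would instead lower MDt with fiber loss,
the opposite of what is observed in lesions. Covariates and outcomes
mirror a CADASIL-like cohort: age 49.7 (6.5) years, 71% female,
hypertension ~16%, lacunes ~70%, microbleeds ~55%; outcomes follow a
logistic model on standardized mean lesion FW, and hypertension both
shifts FW and independently raises microbleed odds, making it a genuine
confounder that the change-in-estimate step must find.

What the phantom does *not* emulate: scanner artifacts (eddy currents,
EPI distortion, Gibbs ringing, bias fields - preprocessing is out of
scope), anatomical geometry, FLAIR contrast or lesion segmentation noise
(masks are ground truth), and cross-subject anatomical variability
(subjects share one grid). Passing tests therefore demonstrate
correctness of the estimators and the internal consistency of the
pipeline, not robustness to real acquisition artifacts.

## Problem sizes and budgets

Defaults were chosen so a full cohort analysis runs on one CPU in
minutes: voxel models are fitted inside the WM mask (~1,700 voxels per
subject), which is the region all downstream analyses read from. The
statistical estimators are exercised at scale through
`simulate_regional_cohort()`, a tabular generator with the same
covariate/outcome structure, so properties like confidence-interval
coverage (200 replicates at n = 200) do not require image simulation.

## Known limitations

* The free-water fit's accuracy depends on the tissue-MD prior scale; at
  very low SNR or for tissue far from parenchymal diffusivities the
  estimator inherits the prior's bias. The noise-scaling keeps the
  noiseless limit exact.
* The deconvolution is not algorithm-equivalent to any published
  three-tissue implementation; it is a well-specified constrained
  least-squares formulation of the same model, and the single-shell
  three-tissue degeneracy means GM fractions in nearly isotropic voxels
  are allocation-dependent. AFD, the quantity the analysis consumes, is
  insensitive to that allocation in fiber-bearing voxels (tested against
  ground-truth density, r > 0.9 noiseless).
* `run_pipeline()` executes stages in one process and returns all
  intermediate tables; there is no persistent stage cache. Re-running
  only the statistics means calling the statistics functions on the
  returned `cohort_table`.
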