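---
title: "Methods: resting-state network features and their relation to behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state network features and their relation to behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnet)
```

## The problem

Task-free ("resting-state") fMRI data decompose into a set of spatially
coherent networks whose activity covaries over time. Given one 4D volume per
subject and one behavioural score per subject (here an SSRT-like response-
inhibition score, in ms), the pipeline asks which *features* of those
networks carry individual-difference information:

1. **Amplitude** — the standard deviation of a network's timeseries, one
   number per network per subject;
2. **Network matrices** — the full or partial temporal correlations between
   every pair of network timeseries;
3. **Spatial maps** — the subject-specific voxelwise network weights.

Each feature is correlated with the behavioural score across subjects and
passed through multiple-comparison control suited to its dimensionality:
Benjamini–Hochberg FDR for the scalar features, and threshold-free cluster
enhancement (TFCE) with max-statistic permutation FWE for the maps.

Because a study's raw scans are rarely redistributable, the package ships a
synthetic-data generator that plants all three couplings with known strength,
so the full pipeline is verifiable by parameter recovery on any machine.

## Pipeline stages

### Preprocessing operators

Only the two preprocessing steps that act on already-registered data are
implemented: separable Gaussian spatial smoothing (`gaussian_smooth()`,
FWHM in mm; `sigma = FWHM / (2 sqrt(2 ln 2)) / voxel_size`) and high-pass
temporal filtering (`highpass_filter()`). The high-pass is a least-squares
projection onto an intercept plus discrete-cosine drift terms with period
longer than the cutoff (default 100 s). A projection was chosen over a
running-line smoother because it is idempotent and has an exactly testable
spectral contract; the practical difference for drift removal is negligible.
Smoothing uses zero-padded borders — the natural convention for masked brain
data whose background is zero — and is applied in unmasked volume space, then
re-masked.

### Group ICA

`group_ica()` performs temporal-concatenation group ICA at a *fixed*
dimension `d` (a config parameter; published analyses of this kind use
values like 27 or 70). Subjects are demeaned over time and stacked; each
voxel is then variance-normalized by an estimate of its *noise* standard
deviation — the residual sd after a first-pass rank-`d` PCA fit, floored at
`1e-6` of the largest voxel sd. Normalizing by noise rather than total
variance matters: dividing by total sd flattens the very structure ICA is
meant to find, and on noise-free data it would divide by numerical residue.
The floor makes the operator well-defined in the noiseless limit (all voxels
then share one scale).

The reduced matrix is exactly whitened over voxels, and maximally
non-Gaussian spatial components are estimated by a symmetric (parallel)
fixed-point iteration with the log-cosh (tanh) contrast, `tol = 1e-6`,
`max_iter = 500`. Non-convergence returns the current estimate with a
warning and a `converged = FALSE` flag. Each component's sign is fixed so
its skewness is nonnegative, and components are ranked by the variance of
the concatenated data they explain (stable sort; ties keep the original
index). Signal/artifact labels are supplied explicitly
(`set_component_labels()`) — in real data by the analyst, in simulations from
the ground truth — replacing visual classification.

### Dual regression

Stage 1 (`stage1_timeseries()`): the group maps are demeaned and scaled to
unit variance over voxels, and all `d` of them — signal *and* artifact —
jointly regress every volume, giving the subject's raw network timeseries.
Stage 2 (`stage2_maps()`): the timeseries are demeaned and scaled to unit
variance over time and regress every voxel, giving the subject's beta maps
and the residual sd per voxel. "Normalized" is read as unit-variance scaling
throughout (sample convention, denominator `n - 1`), matching the common
dual-regression convention; the residual sd uses denominator `t` because it
estimates the background-noise scale rather than a dof-corrected variance —
the choice only rescales z-maps monotonically. The z-maps divide each beta by
the residual sd (`z_transform_maps()`); voxels with zero residual sd map to
zero and are counted.

**Amplitude** is the sample sd of the *raw* stage-1 timeseries, taken before
the stage-2 normalization — normalizing first would erase exactly the
quantity of interest.

### Network matrices

All estimators consume the stage-1 timeseries of **all** components, so that
artifact variance is conditioned away; rows/columns touching artifact
components are discarded only at the inference step.

* `netmat_corr()` — pairwise Pearson correlation (CORR).
* `netmat_icov()` — L1-penalised Gaussian maximum likelihood (graphical
  lasso, written here as block coordinate descent with an off-diagonal
  penalty) on the sample correlation matrix, reported as partial correlations
  `-Theta_ij / sqrt(Theta_ii Theta_jj)` with zero diagonal (ICOV). The
  penalty is `rho = lambda / 1000`, so the conventional working value
  `lambda = 10` gives `rho = 0.01` on the correlation scale; the sweep
  `lambda in {5, 10, 20, 50, 100, 200}` then spans light to heavy shrinkage
  and reproduces the expected ordering (heavier penalty, smaller and sparser
  partial correlations). At `lambda = 0` the estimator converges to the
  closed-form inverse-correlation partial correlation.
* `netmat_gicov()` — group-regularized variant: each subject's covariance is
  shrunk toward the group mean, `S*_s = (1 - tau) S_s + tau mean(S)`
  (default `tau = 0.5`), then the ICOV estimator is applied per subject.
  This convex shrinkage construction captures "regularize across subjects"
  with testable endpoints (`tau = 0` is per-subject ICOV, `tau = 1` complete
  pooling) without reproducing any particular joint-likelihood objective.

`fisher_z()` applies atanh off-diagonal before cross-subject correlation, to
improve normality.

### Inference

Scalar features (amplitudes; netmat edges among signal components) are
Pearson-correlated with the score; two-sided p-values come from the t
distribution with `n - 2` df, and BH-FDR is applied within a feature class.
Using two-sided p-values *is* the extra factor-of-two correction for testing
both correlation signs. P-values are pooled within one feature class and one
decomposition only — never across classes.

Spatial maps use `permutation_fwe()`: the behaviour vector is permuted
across subjects (`n_perm` times; all `n!` enumerated exactly when feasible,
identity always included), each permuted correlation map is converted to t,
enhanced by TFCE, and its maximum recorded. The per-voxel FWE-corrected p is
the fraction of permutation maxima at or above the observed enhanced value —
never zero by construction. Two-sided inference runs each sign against its
own max-statistic null and doubles the smaller p (capped at 1). TFCE uses the
standard published parameters `E = 0.5`, `H = 2`, 26-connectivity, and
`dh = max(stat)/100` per map.

`overlap_stats()` and `bonferroni_across_rsns()` provide the bookkeeping for
comparing z / non-z map variants (counts and percent overlap of significant
voxels) and for the optional across-network Bonferroni step (e.g.
`0.05 / 16 = 0.0031`).

## The synthetic generator

`simulation_truth()` + `simulate_study()` emulate a small resting-state
study. Defaults describe the desk-scale shape: a 16 x 16 x 8 grid (2 mm
voxels), 30 subjects, 230 timepoints at TR = 2 s, `d_true = 5` compact
Gaussian-blob networks with pairwise normalized overlap below 0.3.

* **Behaviour**: i.i.d. standard normal scores, affinely mapped to an
  SSRT-like scale (mean 220 ms, sd 30 ms). The distribution parameters are
  conventional values for stop-signal studies, not estimates from any
  dataset; every analysis in the package is correlation-based, so the affine
  map is cosmetic. Couplings act on the standardized score `z_s`.
* **Timecourses**: drawn from a zero-mean Gaussian with inverse-covariance
  `precision` (default: a chain — tridiagonal with off-diagonal -0.35 — so
  partial and full correlations genuinely differ), then each column is
  rescaled to the subject's realized amplitude *exactly*.
* **Amplitude coupling**: realized amplitude is
  `alpha_i + beta_i z_s + eta_si`, with `eta` a subject-level dispersion
  (sd `amplitude_noise_sd`). The dispersion term makes the planted
  amplitude-behaviour correlation a real, tunable parameter,
  `beta_i / sqrt(beta_i^2 + sd_eta^2)`; without it the correlation is
  trivially +/-1. Defaults `beta = -0.15` on networks 1-3 and
  `sd_eta = 0.26` plant r = -0.50, the magnitude of the strongest published
  amplitude-behaviour correlations in this literature. Non-positive realized
  amplitudes abort with the component named.
* **Spatial coupling**: on each network's effect mask (the voxels above half
  the blob peak), the subject map weight is `m_i(v) + gamma_i z_s`.
  Defaults `gamma = -0.08` on networks 1-2: against the stage-2 estimation
  noise `~ noise_sd / sqrt(t) ~ 0.066` this plants voxelwise correlations
  around -0.7..-0.8, detectable but not trivial at n = 30.
* **Noise**: i.i.d. Gaussian, homoscedastic across voxels (`noise_sd = 1`),
  matching the ordinary-least-squares assumptions of the regressions.
  An optional low-frequency sinusoid exercises the high-pass filter.

Subjects use seed `seed + subject_index`, so they are independent yet
individually reproducible, and the generator never touches the caller's RNG.

### What the generator does *not* emulate

Head motion, physiological noise, scanner drift beyond the optional
sinusoid, spatial autocorrelation of the sensor noise, registration error,
and heteroscedastic noise. Two consequences matter when reading test
results. First, passing recovery tests show the estimators are correct under
their own assumptions, not that they are robust to artefacts ICA is used to
remove in real data. Second, with homoscedastic noise the stage-2 residual
sd is nearly constant across voxels, so z-maps differ from beta maps mainly
by per-subject estimation noise in the residual sd; the empirical tendency
for original (non-z) maps to yield more significant voxels than z-maps is
therefore present but much weaker here than in real data, where residual
noise varies strongly over space. The corresponding sensitivity-ordering
check holds only in about two-thirds of simulation replicates rather than
the large majority seen with real data.

## Verification strategy and problem sizes

Every estimator is tested against an independent oracle: dual regression
against explicit normal-equations solvers; CORR against a pairwise loop;
ICOV at `lambda = 0` against the closed-form inverse-correlation partial
correlation and a regression-residual oracle; TFCE against brute-force
threshold integration with BFS clustering; BH-FDR against an exhaustive
step-up scan; the permutation engine against exact enumeration at n = 5
(p-values are then exact multiples of 1/120).

Recovery and calibration use simulation at these sizes, chosen to keep the
default test run within minutes on one CPU: amplitude-recovery replicates at
the full default shape (30 subjects, 230 timepoints, 2048 voxels, 100
replicates); FDR null calibration at 8 x 8 x 4 / 60 timepoints (500
replicates); permutation-FWE null calibration at 8 x 8 x 4 / 40 timepoints,
`n_perm = 500` (200 replicates); map-condition orderings at the default
shape with `n_perm = 300` (50 replicates). Replicate loops regress against
the generator's true group maps — ICA source recovery is verified once,
separately, on noiseless mixtures — so that recovery rates measure the
feature-and-inference path rather than compounding ICA matching ambiguity.

With the planted amplitude correlation at its default r = -0.5 and n = 30
subjects, per-network power at the BH-effective threshold is about 0.7, so
exact recovery of all three planted networks with no false positive occurs
in roughly half to two-thirds of replicates; pushing that rate above 90%
would require planting |r| of roughly 0.72 or more. The package keeps the
weaker, literature-scale effect size as the default and reports the recovery
rate as measured.

## Numerical choices and degenerate inputs

* Sample sd (denominator `n - 1`) everywhere except the stage-2 residual sd
  (denominator `t`); both stated above.
* Zero-variance feature columns are excluded from correlation and correction
  with a warning; zero-variance voxels get statistic 0; zero residual-sd
  voxels get z = 0 and are counted.
* Graphical-lasso convergence tolerance `1e-8` relative to the mean
  off-diagonal scale, 500 sweeps max, error on non-convergence; symmetry is
  enforced by averaging with the transpose and asserted.
* The permutation p estimator counts the identity permutation, so p >= 1 /
  n_perm always; rank-deficient designs abort with the collinear columns
  named.
* `fdr_bh()` requires p-values in (0, 1]; an empty vector is an error.

## Worked example

```{r example, eval = FALSE}
truth <- simulation_truth(seed = 1)   # 30 subjects, 5 networks, 3 coupled
study <- simulate_study(truth, n_timepoints = 230)

analysis <- run_rsn_analysis(study$datasets, study$behavior, d = 5, seed = 2)
analysis$amplitude_results            # per-network r, p, FDR flags
analysis$netmat_results               # per-edge results, all three estimators

m <- match_components(analysis$group_maps, truth$group_maps)
si <- spatial_map_inference(analysis$decompositions, m$estimated[1],
                            study$behavior$score, truth$grid,
                            n_perm = 500, seed = 3)
glance(si)
```

## Known limitations

* The ICA objective is plain log-cosh negentropy; no mixture-model inference
  on maps and no automatic model-order selection — `d` is the user's call.
* gICOV is a shrinkage surrogate for joint group covariance modelling; its
  fidelity to any particular joint objective is untested by design.
* The graphical-lasso penalty scaling (`rho = lambda / 1000`) reproduces the
  qualitative lambda ordering; absolute sparsity levels at a given `lambda`
  are implementation-specific.
* Permutation inference assumes exchangeable subjects under the null — no
  nuisance covariates; the design is a plain correlation.
* TFCE connectivity is fixed at 26; no cluster-extent alternative.
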