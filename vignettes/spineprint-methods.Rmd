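---
title: "Fingerprinting spinal cord and brain functional connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting spinal cord and brain functional connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineprint)
```

## The problem

Resting-state functional connectivity (FC) profiles of the human brain are
individually distinctive enough that a person can be recognized from one scan
to the next — the "connectome fingerprint". This package implements the same
test-retest identification machinery for the cervical spinal cord, where
signals are far noisier, regions far smaller, and the existence of a reliable
"spine-print" is the scientific question. Everything downstream of
preprocessing is covered: parcel time-series extraction, FC computation,
the identifiability matrix and its summary statistics, edge-level
reliability maps, PCA-based identifiability maximization, and removal of
shared brain–spine variance before fingerprinting.

## Parcellation

The cervical cross-section is divided into 14 regions: 6 bilateral
gray-matter ROIs (dorsal horn `dh`, intermediate zone `iz`, ventral horn
`vh`) and 8 bilateral white-matter ROIs (corticospinal tract `cst`,
fasciculus cuneatus `fc`, fasciculus gracilis `fg`, spinal lemniscus `sl`).
Each included level (C2–C8) contributes these 14 ROIs, so three levels give
42 ROIs, five give 70, and seven give 98. A brain block defaults to 119 ROIs
(a 100-region cortical atlas plus 19 subcortical areas).

The within-level ROI order (GM `dh`, `iz`, `vh`, then WM `cst`, `fc`, `fg`,
`sl`, each left-then-right) is a package convention: the anatomical scheme
fixes membership but not a serialization order, and a deterministic order is
needed for reproducible matrix layouts. The order can be permuted through
the `scheme` argument of `build_spinal_parcellation()`.

Voxel time series are collapsed to parcel series with a robust mean: at each
time point, only voxel values between the 5th and 95th percentiles of that
ROI's instantaneous value distribution are averaged. Two readings of this
trimming are possible (across voxels within a time point, or across time
within a voxel); we trim across voxels, which is the reading that suppresses
spatial outliers such as vessel or edge voxels, and expose the percentile
bounds as arguments. Percentiles use linear interpolation between order
statistics (R's default type 7), and a trim that would discard every voxel
(e.g. a single-voxel ROI) falls back to the plain mean rather than
producing an empty average. tSNR is the voxelwise temporal mean over the
population (n, not n−1) standard deviation, matching common tSNR tooling;
zero-variance voxels yield `NA` rather than an error.

## Fingerprint statistics

For each subject $i$ and run $r \in \{1, 2\}$ the FC matrix
$F_i^r \in [-1,1]^{N \times N}$ holds Pearson correlations between parcel
time series. Its strict upper triangle is unfolded (row-major) into a
profile vector of length $M = N(N-1)/2$. The identifiability matrix
$\mathbf{I} \in \mathbb{R}^{N_s \times N_s}$ correlates run-1 profiles
(rows) with run-2 profiles (columns); it is asymmetric because the two runs
are ordered sets.

* $I_{\text{self}}$: mean diagonal (within-subject similarity across runs).
* $I_{\text{others}}$: mean off-diagonal. Both triangles are pooled — the
  matrix is asymmetric, so each ordered cross-subject pair is a distinct
  observation.
* $I_{\text{diff}} = I_{\text{self}} - I_{\text{others}}$: the fingerprint
  strength.
* Cohen's $d = (I_{\text{self}} - I_{\text{others}}) /
  \sqrt{(\sigma^2_{\text{self}} + \sigma^2_{\text{others}})/2}$ with sample
  variances (n−1) over the diagonal and off-diagonal sets.
* Success rate: the fraction of rows whose strict maximum falls on the
  diagonal. An exact tie with an off-diagonal entry counts as a failure and
  raises a warning — ties are measure-zero in floating-point pipelines, but
  the convention must be deterministic.
* Top-K accuracy: fraction of rows whose diagonal entry ranks within the K
  largest row values (ties broken by lower column index); non-decreasing in
  K by construction and equal to the success rate at K = 1.
* Chance level: $100/N_s$ percent, reported rounded to one decimal.

Identification is row-wise (run-1 queries against the run-2 gallery), which
is the convention stated for the method; `fingerprint(symmetric = TRUE)`
averages the two directions for users who prefer a direction-free summary.
Percentages are reported rounded to one decimal but retained unrounded in
every result object. FC values enter the profile raw: no Fisher
z-transform is applied by default (`fc_vectors_of_runs(fisher_z = TRUE)`
enables it), no smoothing, no thresholding.

## Edge reliability: ICC(1,1)

Per edge, the two runs of the $N_s$ subjects form an $N_s \times 2$ table
analyzed with the one-way random-effects ANOVA:

$$\mathrm{ICC}(1,1) = \frac{MSR - MSW}{MSR + (k-1) \, MSW}, \qquad k = 2,$$

where $MSR$ is the between-subject mean square (df $N_s - 1$) and $MSW$ the
within-subject mean square (df $N_s(k-1)$). For $k = 2$ the value lies in
$[-1, 1]$; negative estimates are retained, not floored, since the
estimator admits them and flooring would bias averages upward. Edge maps
are symmetrized back into the $N \times N$ layout with an undefined
diagonal.

Cross-level summaries average the within-level $14 \times 14$ diagonal
blocks elementwise across levels and datasets (between-level edges are
excluded; the summary is a cross-sectional map). Thresholding retains edges
at or above the 95th percentile of the defined strict-upper-triangle values
— each edge counted once — and nodal strength sums the retained values per
ROI (row sums, diagonal excluded). Because one report convention describes
this reduction as a mean rather than a sum, `nodal_strength()` exposes both
(`reduce = "sum"` is the default).

## PCA-based Idiff maximization

All $2 N_s$ profile vectors are stacked as observations, centered by the
mean profile, and decomposed once by SVD. For each component count $m$ the
profiles are reconstructed from their leading $m$ components plus the mean,
and Idiff is recomputed; the selected $m^\*$ is the smallest $m$ attaining
the maximum. Since the default sweep range includes full rank (where
reconstruction is exact), $\mathrm{Idiff}(m^\*)$ can never fall below the
unreconstructed Idiff. The intuition: run-specific noise spreads across
low-variance components, so truncating them preserves subject structure
while discarding what differs between runs. Sign indeterminacy of the SVD
is fixed by making the largest-magnitude loading of each component
non-negative, keeping sweeps bit-reproducible. Centering over observations
(subtracting the mean profile edge-wise) follows the established PCA
identifiability framework.

## Brain–spine residualization

With simultaneous brain and cord acquisition the two blocks share a time
axis, and a linear model $Y = X\beta + \varepsilon$ removes the variance of
one block linearly explained by the other. Both sides are demeaned instead
of fitting an intercept — band-passed fMRI series are mean-free, and
demeaning keeps the decomposition $Y = \hat{Y} + \varepsilon$ exact while
the residuals stay orthogonal to every predictor. $\beta$ is the
minimum-norm least-squares solution via SVD pseudoinverse, so rank-deficient
predictor blocks (e.g. more brain ROIs than independent time points) remain
well-defined and deterministic. The fit is per subject and per run
independently; no pooling across runs is performed. When the predictor
count reaches the number of time points the fit is perfect and residuals
vanish — the pipeline warns about this overfit regime, and refuses to
fingerprint residuals that are numerically zero.

`residual_fingerprint()` then runs the full fingerprint machinery on the
residual FC profiles, in either direction (`spine_given_brain` quantifies
spinal identifiability not linearly explained by the brain, and
conversely).

## The synthetic cohort generator

No public dataset is required: `generate_cohort()` emulates the structure
the analyses rely on — $N_s$ subjects × 2 runs of parcelled time series
with subject-stable covariance plus run-level noise.

Subject $i$'s loading matrix is $A_i = A_{\text{group}} + \lambda \, B_i$
($N \times k$, standard normal entries), giving the covariance
$C_i = A_i A_i^\top + \sigma^2_{\text{obs}} I$ — positive definite by
construction, with $\lambda$ (`lambda_subject`) the single knob for subject
distinctiveness. Each run perturbs $C_i$ by
$\sigma_{\text{run}}(S + S^\top)/2$ with $S$ standard normal, floored
eigenvalue-wise at $10^{-6}$ of the leading eigenvalue (the factor
construction was chosen over ad-hoc correlation-matrix repair precisely to
avoid indefinite matrices), and draws $T$ i.i.d. multivariate-normal time
points. In combined brain+spine cohorts the two blocks receive
**independent** base factors, so the base covariance is block-diagonal;
cross-block dependence enters only through an explicit per-run latent
signal with subject-specific loadings, added fully to the brain block and
scaled by `coupling` $\in [0,1]$ into the spine block. This makes the
coupled component exactly the part of spinal variance a brain regression
can remove, which is the mechanism the residualization analyses probe.

All randomness flows from one integer seed through counter-based
per-subject/per-run substreams, so cohorts are byte-reproducible and adding
subjects leaves earlier subjects' data unchanged.

Defaults are chosen to resemble a single-session spinal study: 15 subjects,
42 ROIs (levels C4–C6), 300 time points per run, 5 latent factors,
`lambda_subject = 1`, `sigma_run = 0.3`, `sigma_obs = 1`. The generator
emulates subject-stable second-order structure only: it does not simulate
voxel-level images, physiological noise spectra, CSF pulsatility, motion,
or spatial autocorrelation. Passing tests therefore demonstrate that the
*analysis machinery* behaves correctly on data with the assumed covariance
structure — not that real spinal-cord acquisitions carry a fingerprint of
any particular strength.

## Study-condition checks and problem sizes

The test suite validates behavior under four regimes, with sizes picked to
exercise the statistics at realistic dimensionality:

* **Null** (`lambda_subject = 0`): subjects are exchangeable, so
  identification accuracy must sit at the $100/N_s$ chance level. Verified
  over 200 replicate cohorts (15 subjects, 42 ROIs, 300 time points) within
  three binomial standard errors, and cross-checked by 200 random-matrix
  permutation replicates at $N_s = 18$, 43 and 15.
* **High distinctiveness** (`lambda_subject = 4`, `sigma_run = 0.1`):
  accuracy reaches ≥ 95% and Idiff exceeds 0.2.
* **Monotonicity**: seed-averaged Idiff is non-decreasing in
  `lambda_subject` and non-increasing in `sigma_run` over a parameter grid.
* **Coupling** (12 subjects, 119 brain + 42 spinal ROIs, 600 time points,
  `lambda_subject = 0.5`, `sigma_run = 1`): with `coupling = 0.8`,
  spine-residual Idiff falls below spine-only Idiff (sign test over 50
  seeds); with `coupling = 0` the difference is statistically
  indistinguishable from zero. The 600-point runs matter here: regressing
  119 predictors out of short runs inflates a mechanical reliability loss
  (degrees-of-freedom cost) that would confound the coupling effect.

Exact analytic identities (oracle equivalence of Idiff, Cohen's d,
ICC(1,1) and the regression against brute-force computations; full-rank PCA
reconstruction; vectorization round-trips) are held to 1e−10 or tighter.

## Numerical conventions and edge cases

* Quantiles everywhere use linear interpolation (type 7).
* Asymmetry beyond 1e−10 in a matrix offered for vectorization is an error,
  not silently symmetrized.
* Constant ROI columns abort FC computation with the ROI named.
* Cohen's d with zero variance in both similarity sets returns `NA` with a
  warning instead of dividing by zero.
* ICC denominators of zero return `NA`; undefined entries are excluded from
  averages and thresholds.
* Ties: row-maximum ties count as identification failures (warned);
  top-K ranking breaks ties by lower column index; the PCA sweep breaks
  Idiff ties by the smaller component count.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(
  n_subjects = 15,
  parcellation = build_spinal_parcellation(c("C4", "C5", "C6")),
  n_timepoints = 300, lambda_subject = 1, sigma_run = 0.5, seed = 42)
cohort <- generate_cohort(spec)
result <- fingerprint_cohort(cohort)
print(result)
```

## Known limitations

* Static FC only: no dynamic or partial-correlation variants.
* Two runs within one session; multi-session ($k > 2$) ICC designs and
  other ICC forms (2,1)/(3,1) are out of scope.
* The residual model is linear and instantaneous; lagged or nonlinear
  brain–spine dependencies are not captured.
* The generator's Gaussian factor model is a stand-in for real
  physiological structure; none of its distributional choices are claims
  about spinal-cord biology.
* Image preprocessing (motion correction, registration, physiological
  denoising) must happen upstream; the package starts at voxel data already
  in a common space with ROI labels, or directly at parcelled TSV tables.
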