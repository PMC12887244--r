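# spineprint

Test–retest functional-connectome fingerprinting for spinal cord and brain
fMRI.

## What this is for

Functional connectivity (FC) — the matrix of Pearson correlations between
regionally averaged fMRI time series — is individually distinctive enough in
the brain that a person can be re-identified across scans. `spineprint`
brings the full identification toolkit to the cervical spinal cord, where
tiny ROIs and low tSNR make the existence of a reliable "spine-print" a real
question, and to combined brain+cord acquisitions where the two structures'
shared variance can be separated out. It is aimed at researchers who already
have preprocessed, template-registered data (or want to validate methods on
synthetic cohorts) and need the statistics, not the image preprocessing.

## The statistics at its core

For subject *i* and run *r* ∈ {1,2}, the FC matrix `F_i^r` (N×N) is unfolded
into its strict upper triangle, a profile of length M = N(N−1)/2. The
**identifiability matrix** `I` (Ns×Ns, asymmetric) correlates run-1 profiles
(rows) with run-2 profiles (columns). From it:

- **Iself** = mean diagonal, **Iothers** = mean off-diagonal,
  **Idiff = Iself − Iothers** — the fingerprint strength;
- **Cohen's d** = (Iself − Iothers) / √((σ²self + σ²others)/2);
- **identification accuracy** — the percentage of rows whose maximum falls
  on the diagonal (chance = 100/Ns %), plus the lenient **top-K** curve;
- **ICC(1,1)** per edge — the one-way random-effects intraclass correlation
  (MSR − MSW)/(MSR + (k−1)MSW) with k = 2 runs — mapped back to N×N,
  thresholded at the 95th percentile and summarized as nodal strength;
- **PCA Idiff maximization** — reconstruct all 2·Ns profiles from their top
  *m* principal components and pick the *m* that maximizes Idiff;
- **residualization** — per subject/run, regress the spinal time series on
  the brain block (or vice versa), `Y = Xβ + ε`, and fingerprint the
  residual FC.

Spinal parcellations follow the canonical cervical cross-section: 14 ROIs
per level (bilateral dorsal horn, intermediate zone, ventral horn in gray
matter; corticospinal tract, fasciculus cuneatus, fasciculus gracilis,
spinal lemniscus in white matter), so C4–C6 → 42 ROIs, C4–C8 → 70,
C2–C8 → 98; the default brain block has 119 ROIs.

A seeded synthetic-cohort generator (`cohort_spec()` / `generate_cohort()`)
produces Ns subjects × 2 runs with controllable subject distinctiveness,
run noise and brain→spine coupling, so every stage is testable without any
download.

## Worked example

```r
library(spineprint)

spec <- cohort_spec(
  n_subjects = 15,
  parcellation = build_spinal_parcellation(c("C4", "C5", "C6")),
  n_timepoints = 300, lambda_subject = 1, sigma_run = 0.5, seed = 42)
cohort <- generate_cohort(spec)

result <- fingerprint_cohort(cohort)
print(result)
#> Identifiability over 15 subjects
#>   Iself  = 0.9706   Iothers = 0.1809   Idiff = 0.7896
#>   Cohen's d = 20.48
#>   accuracy = 100.0% (15/15 correct, chance 6.7%)
#>   top-K: K=1: 100.0%, K=2: 100.0%, K=3: 100.0%, K=4: 100.0%, K=5: 100.0%
```

Every subject's run-1 profile correlates most with their own run-2 profile
(accuracy 100% against a 6.7% chance level), self-similarity (0.97) far
exceeds cross-subject similarity (0.18), and the separation is enormous in
standard-deviation units — this cohort was generated with a strong subject
effect, so the pipeline should and does recover it.

```r
rl <- lapply(cohort$runs, `[[`, 1); r2 <- lapply(cohort$runs, `[[`, 2)
v1 <- lapply(rl, function(r) vectorize_fc(compute_fc(r)))
v2 <- lapply(r2, function(r) vectorize_fc(compute_fc(r)))

print(icc_matrix(v1, v2))
#> ICC(1,1) map: 42 ROIs, 861 edges; mean 0.959, max 0.994

print(idiff_sweep(v1, v2))
#> PCA Idiff sweep over m in [2, 30]
#>   m* = 14 with Idiff = 0.8156 (full rank: 0.7896)
```

Edges are highly test-retest reliable here (mean ICC 0.96), and truncating
the profiles to their top 14 principal components lifts Idiff from 0.790 to
0.816 by discarding run-specific noise components.

`run_pipeline(pipeline_config(...))` chains all stages (simulate or TSV
input → FC → fingerprint → ICC → PCA sweep → residualization) and writes a
JSON report plus TSV matrices; `inst/cli/spineprint.R` is a thin Rscript
wrapper with `run`, `simulate` and `extract` subcommands.

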