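Package: spineprint
Title: Functional-Connectome Fingerprinting for Spinal Cord and Brain fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Test-retest functional-connectivity fingerprinting for parcelled
    spinal cord and brain fMRI time series. Builds spinal cross-sectional
    parcellations (14 gray/white-matter regions per cervical level), extracts
    robust-mean parcel time series and tSNR from voxel data, computes Pearson
    functional-connectivity matrices and their vectorized profiles, derives
    the run-1 by run-2 identifiability matrix with Iself, Iothers, Idiff,
    Cohen's d, identification accuracy and top-K curves, maps edge test-retest
    reliability with ICC(1,1) including percentile thresholding and nodal
    strength, maximizes Idiff by PCA reconstruction of connectivity profiles,
    and removes shared brain-spine variance by linear residualization before
    fingerprinting. Includes a seeded synthetic two-run cohort generator with
    controllable subject distinctiveness, run noise and brain-to-spine
    coupling, so the full pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
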