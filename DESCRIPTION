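Package: smallheart
Title: Small-Heart-Corrected Quantification of Gated Myocardial Perfusion SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of left-ventricular volumes, ejection fraction and
    diastolic filling indices from gated myocardial perfusion SPECT, with a
    volume-dependent epicardial edge-shift correction that reduces the
    systematic underestimation of end-systolic volume (and overestimation of
    ejection fraction) in small hearts. The left ventricle is delineated by
    iterative normal-profile fitting of a closed mid-myocardial surface, with
    endocardial and epicardial surfaces placed symmetrically about the
    maximal-count surface. Includes a digital beating/breathing prolate-
    spheroid phantom, a parallel-beam projector with Poisson noise, OSEM
    reconstruction and Gaussian post-filtering, so that volume and ejection
    fraction recovery can be validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
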