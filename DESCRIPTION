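Package: gpdcnet
Title: Effective Connectivity of Resting-State Networks via Generalized
    Partial Directed Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for frequency-domain effective
    connectivity in resting-state fMRI network time courses: temporal
    preprocessing (band-pass filtering, CompCor-style confound regression,
    motion-outlier censoring), group spatial ICA with MDL component-number
    estimation and template-based network labelling, voxelwise functional
    connectivity statistics with permutation cluster-level FWE correction,
    multivariate autoregressive (MVAR) modelling with AIC order selection,
    generalized partial directed coherence (GPDC) band-averaged into
    directed edge matrices, edge-wise group inference with
    Benjamini-Hochberg FDR, phase-randomization surrogate edge detection,
    and Pearson correlation of causal strength with clinical scores. A
    synthetic-data generator produces two-group by two-session studies
    driven by known stable VAR causal graphs so that every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
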