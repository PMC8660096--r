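Package: tvpsDFA
Title: Long-Range Temporal Correlations of Time-Varying Phase Synchrony
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detrended fluctuation analysis (DFA) of time-varying phase
    synchrony between band-limited neural source signals. Provides canonical
    EEG frequency bands with Hamming-window FIR band-pass filtering,
    Hilbert-transform phase extraction and unwrapping, the rate-of-change
    phase-difference (TV-PS) series for all region pairs, DFA with
    log-spaced overlapping windows and linear detrending, maximum-likelihood
    model selection (ML-DFA) validating scale-invariance of fluctuation
    plots against twelve alternative models, and the network-based statistic
    (NBS) for group inference on subject-by-edge exponent matrices with a
    nuisance covariate and permutation-derived family-wise error control.
    Includes an exact circulant-embedding fractional Gaussian noise
    simulator and a synthetic cohort generator with known ground-truth
    Hurst exponents and planted connectome effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: TimeCourse, Electrophysiology, StatisticalMethod, Network
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bands.R'
    'dfa.R'
    'fgn.R'
    'io.R'
    'mldfa.R'
    'nbs.R'
    'phase.R'
    'pipeline.R'
    'synthetic.R'
    'tvpsDFA-package.R'
    'utils.R'
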