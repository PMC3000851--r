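Package: sputumFTIR
Title: FTIR Sputum Spectral Screening for Lung Cancer Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating lung cancer from normal sputum using
    Fourier transform infrared (FTIR) absorbance spectra of sputum cell
    pellets. Implements the full discovery pipeline: two-point linear
    baseline correction, fingerprint-region cropping (950-1800 1/cm),
    vector normalization, nine-point Savitzky-Golay second derivatives,
    per-wavenumber nonparametric screening (Mann-Whitney U with Holm
    sequential Bonferroni correction), matching of significant wavenumbers
    to second-derivative band centres with mucin-band exclusion, and
    multivariate analysis by UPGMA hierarchical clustering on correlation
    distances and principal components analysis with a variance-fraction
    retention rule. A synthetic cohort generator produces labelled
    cancer/normal spectra with configurable band structure, baseline
    drift, multiplicative gain, subject-level amplitude jitter and
    additive noise, so that every pipeline stage is testable without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'preprocess.R'
    'wavenumber-stats.R'
    'multivariate.R'
    'pipeline.R'
    'spectra-io.R'
    'synthetic.R'
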