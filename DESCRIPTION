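Package: quenchfit
Title: Two-State Analysis of Reversible Fluorescence Quenching by Metal Ions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of reversible fluorescence quenching of
    dye-labelled, bipyridine-bearing DNA probes by transition-metal ions.
    Provides closed-form quenching models (Stern-Volmer, approximate and
    exact mass-balance two-state models), weighted nonlinear fitting of
    ensemble titrations to extract stability constants and residual quantum
    yields, Benesi-Hildebrand analysis of absorbance titrations,
    decomposition of single-molecule blinking traces into background, dim
    and bright states by three-Gaussian histogram fits, Forster radius
    computation from emission and extinction spectra, and synthetic-data
    generators so that every stage of the pipeline can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
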