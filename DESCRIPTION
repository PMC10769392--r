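Package: enseq
Title: Ensemble Consistency Analysis for Genomic Sequence-to-Activity Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep-ensemble uncertainty quantification for genomic
    sequence-to-activity prediction. Provides a synthetic ground-truth
    regulatory model and seed-perturbed replicate predictors, ensemble
    sign-probability and consistency classification, Poisson-null peak
    calling with FDR control, in-silico transcription-factor motif
    insertion and mutagenesis scoring, eQTL-style variant effect (SAD)
    analysis, and personal-genome expression prediction with
    cross-individual correlations and driver-variant identification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
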