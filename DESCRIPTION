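Package: synaptoform
Title: Neuron-Type-Specific Postsynaptic Proteomics and Proteoform Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neuron-type-specific postsynaptic
    proteomics from isobaric (TMT) reporter-ion quantification. Provides
    protein-level summarisation and reference-set channel normalization,
    compositional renormalization of phosphopeptide intensities, protein-level
    (one-tailed Welch t) and peptide-level (two-way ANOVA interaction)
    differential analysis, a supervised random-forest construction of a
    postsynaptic proteome library with ROC evaluation and class-specific FDR,
    and peptide-to-exon proteoform fingerprinting (in-silico tryptic
    digestion, exon and junction mapping, gel-slice molecular-weight gating,
    exon detection-frequency tables and distance-based isoform assignment).
    A synthetic-data generator with known ground truth emulates the
    multiplexed reporter-ion designs the methods target, including genotypes
    defined by exon deletions that silence specific peptide subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    randomForest,
    car,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
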