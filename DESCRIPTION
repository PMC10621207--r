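Package: hrdsig
Title: Likelihood-Based Homologous Recombination Deficiency Classification
    from Mutational Spectra and Transcriptional Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies exome-sequenced tumours as homologous recombination
    deficient (HRD) from their somatic mutation catalogs. Single-base
    substitutions are binned into the 96 trinucleotide-context categories and
    small insertions/deletions into the 83-category indel scheme; samples are
    assigned to signature-phenotype clusters by Bayes' theorem against
    cluster mean spectra, and p(HRD) is the posterior mass on HRD-associated
    clusters. Includes exome/genome spectrum normalization, non-negative
    least-squares signature exposure fitting, model-based clustering of
    exposure profiles, downsampling and indel-weighting simulation studies,
    a consensus multinomial elastic-net gene selection plus nearest-centroid
    correlation scoring of bulk and single-cell expression, and synthetic
    data generators for end-to-end testing without external cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    Matrix,
    mclust,
    methods,
    pracma,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
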