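Package: indelrisk
Title: Pathogenicity and Functional Impact of Non-Frameshifting Protein Indels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the pathogenicity of non-frameshifting insertion, deletion
    and complex indel variants on protein sequences with an ensemble of bagged,
    class-balanced two-layer feed-forward neural networks trained by resilient
    propagation over engineered sequence, conservation, homolog and
    predicted-functional-site features. Beyond a single pathogenicity score,
    the package reports which structural and functional mechanisms a variant
    disrupts, using empirical P-values against a putatively neutral null with a
    class-prior correction suited to positive-unlabeled training data, and
    cohort-level enrichment statistics (trend value, Fisher's exact test with
    Bonferroni correction, recurrence stratification). A seeded synthetic-data
    generator with planted functional sites makes every step testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
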