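Package: satdyn
Title: Satellitome Quantification and Evolutionary Dynamics of Satellite DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies satellite DNA (satDNA) family abundance and divergence
    from low-coverage paired-end reads or chromosome-level assemblies.
    Provides tandem-aware local alignment of sequences to circular monomer
    consensus libraries, per-hit Kimura 2-parameter divergence,
    divergence-binned repeat landscapes, z-score based classification of
    per-family gain, loss and homogenization, superfamily grouping by
    all-to-all homology, self-dotplot tandem periodicity detection, and
    chromosome-level satellite distribution profiles. Includes a synthetic
    tandem-repeat genome and paired-end read simulator with a full ground
    truth table, so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
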