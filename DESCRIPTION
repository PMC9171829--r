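Package: speccons
Title: Consensus Spectrum Generation for Clustered Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds representative (consensus) spectra for clusters of
    tandem mass spectra using four established strategies: intensity-weighted
    spectrum averaging (AVERAGE), fixed-grid m/z binning with a member
    occupancy filter (BIN), medoid selection by summed pairwise dot-product
    similarity (MOST), and selection of the best-identified member (BEST).
    Includes readers and writers for MGF peak lists, cluster-assignment
    tables, and peptide-spectrum match tables; cluster-quality statistics
    (majority-peptidoform filtering, high/low-quality representative
    classification, cluster-size-stratified score summaries, and
    between-method corroborative/divergent comparison of modification
    sites); and a seeded simulator of replicate-spectrum clusters for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
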