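Package: silkscreen
Title: Proteome-Guided Screening of Silk-Like Structural Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens transcriptome-derived protein catalogues for silk-like
    structural proteins using replicate label-free proteomics, imperfect
    tandem-repeat detection, local-alignment novelty and cross-species
    conservation searches, and Kyte-Doolittle hydropathy profiling. Candidates
    must lack similarity to a known-protein database, be supported by multiple
    tryptic peptides, be detected consistently across replicates, and carry
    substantial repetitive content; survivors are clustered into families,
    grouped by conserved N-termini, and ranked by iBAQ abundance. A synthetic
    study generator plants motif-grammar silk proteins (GA/GAGAGS-type,
    serine-rich, GPX collagen-like, cysteine-rich) among globular decoys with
    replicate peptide intensities and multi-species transcript tables, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
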