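Package: mimoprofile
Title: Mimotope Immunoprofiling of Random-Peptide Phage Display Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of antibody epitope repertoires measured by
    random 12-mer peptide phage display deep sequencing. From per-sample
    peptide read-count tables the package computes top-k cosine-similarity
    immunoprofile QC, discovers group-discriminative gapped motifs scored by
    hypergeometric enrichment, selects features with log-abundance t-tests and
    Youden-optimal cutpoints, annotates motifs against a reference linear
    epitope database with a composition-preserving permutation null and FDR
    control, quantifies per-epitope seroreactivity (normalization, summation,
    log transform, rank tests, t-SNE/DBSCAN clustering), and builds a
    permutation-validated logistic classifier with cross-validated ROC
    analysis. A synthetic cohort generator with planted motifs provides a
    fully reproducible benchmark of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
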