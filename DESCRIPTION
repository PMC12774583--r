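Package: caddforge
Title: Species-Agnostic CADD-Style Deleteriousness Scores from Genome
    Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Combined Annotation Dependent Depletion (CADD) style
    per-variant deleteriousness scores for any species from a reference
    genome, a multiple alignment containing an inferred ancestral sequence,
    and optional population allele frequencies. The pipeline extracts the
    ancestral allele at every reference position, derives proxy-neutral
    variants (ancestor/reference differences fixed in the population),
    simulates an equal number of proxy-deleterious variants from local
    ancestor-to-reference substitution rates, joins user-supplied and
    built-in annotations into an encoded and imputed feature matrix, trains
    an L2-penalised logistic classifier with stratified cross-validation,
    and PHRED-scales the ranked scores of all possible single-nucleotide
    variants. A seeded synthetic-fixture generator emulates every input
    format with known ground truth so the whole workflow is testable at toy
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
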