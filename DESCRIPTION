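Package: dcas9mut
Title: Mutation Spectrum and Frequency Analysis for dCas9 R-Loop
    Mutagenesis Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mutagenesis induced by catalytically dead
    Cas9 (dCas9) binding at a reporter gene, as assayed by selection of
    loss-of-function mutants (e.g. canavanine-resistant can1 mutants in
    yeast). Parses compact per-isolate mutation notation, classifies
    mutation spectra relative to guide-RNA protospacer coordinates with
    explicit target/non-target strand bookkeeping, detects complex
    mutation clusters and homopolymer-associated indels, estimates
    mutation frequencies from selective/nonselective plating counts with
    exact two-tailed Mann-Whitney U testing, scores guides by their
    complement of inactivating non-target-strand cytosines, and provides
    a seeded forward simulator of isolate tables and colony-count data
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
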