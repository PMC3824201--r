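Package: secretr
Title: Archaeal Secretome Inference from Signal Peptides and Peptide Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of archaeal N-terminal signal peptides
    (signal peptidase I substrates, lipoproteins bearing a lipobox, and class
    III prepilin-like substrates) with cleavage-site prediction, filtering of
    replicated mass-spectrometry peptide evidence, label-free protein
    quantification by the exponentially modified protein abundance index
    (emPAI) over an in-silico tryptic digest, and cleavage-aligned residue
    composition statistics. Includes a generator of labelled synthetic
    proteomes and replicate-structured peptide evidence for end-to-end
    validation, and a pipeline that turns a proteome FASTA (plus optional
    evidence tables) into a secretome report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
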