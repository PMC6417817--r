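Package: kircn
Title: Unsupervised KIR Gene Copy Number Calling from Short-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls germline copy number of the highly homologous killer
    immunoglobulin-like receptor (KIR) gene cluster from short-read
    sequencing cohorts. Builds an index of k-mers unique to each gene
    across all of its alleles, counts canonical k-mer occurrences in
    candidate reads, normalizes counts against a background panel of
    random genes, segments the population density of per-gene
    frequencies into copy-number intervals with kernel density
    estimation, and infers co-segregating genes that carry no unique
    k-mers. Includes population-frequency validation, inhibitory-gene
    burden survival analysis, and a synthetic-cohort simulator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    Rcpp,
    Rsamtools,
    jsonlite,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
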