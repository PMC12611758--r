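Package: duplexome
Title: Duplex Consensus Mutation Calling, Burden and Selection Analysis for Polyclonal Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis stack for targeted single-molecule duplex sequencing of
    polyclonal tissues. Implements duplex consensus calling from read bundles
    with a configurable filter battery (consensus quality, germline and mask
    filters, read-positional Kolmogorov-Smirnov artefact test), three variant
    allele fraction estimators, trinucleotide-corrected mutation burdens with
    Poisson and site-bootstrap confidence intervals, mutational catalogues
    (SBS96, transcriptional strand-wise 192, T>C pentanucleotide 256, DBS78,
    ID83) with opportunity correction and maximum-likelihood signature
    exposure fitting, and dN/dS selection inference at the gene, site and
    within-gene site-set level with duplex coverage correction, one-sided
    negative-selection tests, driver-fraction and mutant-cell-fraction
    estimators. Ships a synthetic polyclonal-tissue and read-bundle simulator
    with truth tables used as the test harness for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    stringi,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
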