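Package: indelbias
Title: Alignment Ambiguity and Aligner Bias at INDEL Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates all optimal pairwise alignments between reads bearing
    alternative alleles and a reference genome, under both an equal-penalty and
    an affine gap model, and uses the enumeration to quantify INDEL
    representation ambiguity. Per-locus "INDEL complexity" (the number of
    co-optimal alignments) is computed from a variant profile, synthetic reads
    are generated around each locus, and recorded INDEL representations are
    tested for aligner bias by comparing observed agreement with the profile
    against the agreement expected under a uniform choice among co-optimal
    alignments, with a Chebyshev-Cantelli tail bound as p-value bound. Includes
    a fully ground-truthed synthetic data generator (reference with tandem
    repeat contexts plus an INDEL profile recorded under a configurable
    alignment convention) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
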