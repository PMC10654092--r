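Package: prophagr
Title: Prophage and Phage-Satellite Discovery in Draft Bacterial Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for locating temperate phage elements in draft bacterial
    genome assemblies. Detects intact prophages by nucleotide similarity to a
    reference phage database, stitches prophages split across unjoined contig
    ends back into single sequences, scans gene annotations with a 15-gene
    sliding window to classify integrated elements, phage-related regions,
    candidate phage-inducible chromosomal islands (PICIs) and defective
    prophages, reconstructs attB/attP attachment sites from core direct
    repeats, clusters proteins into gene phamilies and genomes into clusters by
    shared gene content, and mines phage-encoded ESX-secreted toxin (PEST)
    cassettes via iterative gene-neighborhood networks. Ships a deterministic
    synthetic-genome generator with planted ground truth for end-to-end
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
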