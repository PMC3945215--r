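Package: arscan
Title: Mapping and Characterization of Yeast Replication Origins from
    High-Throughput ARS Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for mapping DNA replication
    origins in budding yeast from functional screen and sequencing data:
    assembly and filtering of autonomously replicating sequence (ARS)
    screen fragments into contigs with inferred functional cores,
    position-weight-matrix motif scanning against a high-order Markov
    background with mixture-model classification of origins into GC- and
    AT-classes, deep-mutational-scanning enrichment analysis of origin
    elements, S/G1 sort-seq replication-timing profiles with peak
    calling, nucleosome-occupancy metaprofiles from MNase fragments, and
    the association statistics tying these layers together.  A bundled
    synthetic-data generator plants origins with known coordinates,
    classes, firing times and nucleosome-depleted regions so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    mclust,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
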