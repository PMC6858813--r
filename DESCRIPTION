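Package: mirclust
Title: Hydrogen-Bond Scoring and Cluster Analysis of miRNA Binding Sites in mRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microRNA (miRNA) binding sites on mRNA transcripts by
    gapless antiparallel hydrogen-bond scoring that admits the non-canonical
    G-U and A-C pairs, filters candidate duplexes by the ratio of their
    hybridization free energy to the miRNA's maximal (fully complementary)
    free energy, and localizes accepted sites to the 5'UTR, CDS or 3'UTR of
    the transcript. Overlapping sites are grouped into clusters by transitive
    interval overlap and summarized with compaction statistics (total site
    length, cluster span, compaction ratio, mean free energy). Includes a
    parser and writer for printed-style site tables with "(n)" multiplicities
    and interval-valued parameters, a seeded synthetic-data generator that
    plants complementary sites with wobble or mismatch corruption and tandem
    repeats, text renderers for duplex interaction schemes and cluster maps,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
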