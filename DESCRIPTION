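Package: crvhotspot
Title: Recurrent Non-Coding Mutation Hotspot Discovery in Cancer Whole
    Genomes
Version: 0.1.0
Authors@R:
    person("Alex", "Doyle", email = "alex.doyle@example.org",
           role = c("aut", "cre"))
Description: Detects recurrently mutated non-coding regions ("hotspots")
    in multi-donor somatic variant sets from cancer whole-genome
    sequencing. Variants are merged by a fixed gap window, scored by
    donor recurrence (D^2/G) weighted by pre-computed per-variant
    functional-impact scores, and tested against an empirical null built
    from hotspots outside putative regulatory regions, with
    Benjamini-Hochberg FDR control. Includes ETS (GGAA) motif offset
    analysis, consensus-derived position weight matrix construction and
    scanning, simple genomic feature annotation, a fully seeded
    synthetic-data generator with planted hotspots for end-to-end
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
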