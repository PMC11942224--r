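Package: broadmark
Title: Narrow and Broad H3K4me3 Domain Analysis from Binned ChIP-Seq Coverage
Version: 0.1.0
Authors@R:
    person("broadmark", "developers", email = "broadmark@example.org",
           role = c("aut", "cre"))
Description: Calls narrow and broad H3K4me3 peaks from binned ChIP-seq
    coverage with a Poisson local-background model (with or without an input
    control), assigns peaks to gene transcription start sites, classifies
    broad domains by a top-percentile width rule, and derives validated lists
    of genes differentially marked between normal and cancer sample groups.
    Includes a synthetic ChIP-seq generator (Poisson background, planted
    narrow ~500 bp and broad >= 4 kb enrichment domains) so the whole
    pipeline is testable without external data, plus readers and writers for
    GTF, BED, narrowPeak, broadPeak, bedGraph and chrom.sizes files and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
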