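Package: corequant
Title: Spectral-Count Quantification and Core-Proteome Analysis for
    Time-Resolved Metaproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking species-level protein expression through a
    biostimulation time series from label-free spectral counts.  Implements
    charge-dependent Xcorr/MSGF peptide-spectrum filtering, single-count
    peptide removal and protein roll-up; length-normalized, log-transformed
    row Z-score quantification with a presence/absence missing-value rule and
    delta-Z differential calls between experiment stages; geochemistry-driven
    binning of samples into stages by average-linkage clustering; a
    reciprocal-best-hit orthology layer yielding core-proteome and
    detected-fraction summaries across genomes; COG-category shift summaries
    and pathway matrix exports; and a fully seeded synthetic-data generator
    that emulates the statistical structure of an acetate-amended aquifer
    proteomics experiment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
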