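Package: twinmosaic
Title: Detection of Postzygotic Mosaic Mutations from Allelic Ratios in
    Monozygotic Twins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative postzygotic (mosaic) single-nucleotide mutations
    by contrasting allelic ratios between monozygotic co-twins sequenced on two
    platforms (high and low read depth). Implements the allelic-ratio-difference
    statistic with its region, double-homozygous-reference, clear-call and
    threshold filters; cross-platform sign matching with an exact binomial test
    and a true-positive-rate estimate; exact and Monte Carlo calibration of the
    false-positive rate under the binomial sampling null; permutation tests for
    positional clustering of candidate loci within and between twin pairs;
    Fisher-exact category enrichment with Benjamini-Hochberg FDR control and a
    same-individual negative control; and a synthetic twin-dataset generator
    with planted mosaic loci, hotspots and annotation categories so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
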