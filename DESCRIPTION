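Package: rdcnv
Title: Read-Depth Detection of Copy Number Variants with Bias Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deletions and duplications from whole-genome sequencing
    read depth without a matched control. Per-base depth is corrected for
    GC bias in both mean and variance by quantile normalization within bins
    of insert-weighted GC content, with separate distributions for low and
    high mapping-quality regions; coverage near biased dinucleotide repeats
    is normalized within distance bins instead. Regions of excessive
    coverage are masked in one of two calling pipelines whose results are
    combined as a union. Candidate breakpoints are screened per base and
    tested with a size-varying sliding-window z-statistic to improve
    breakpoint resolution. Includes a deterministic synthetic-data
    generator (reference plus aligned reads with controllable GC bias,
    repeat suppression, coverage hotspots and spiked CNVs) and a benchmark
    scorer based on reciprocal-overlap matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
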