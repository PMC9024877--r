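Package: ssrsurvey
Title: Genome-Wide Survey of Microsatellites and Compound Microsatellites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect microsatellites (SSRs, motif periods 1-6) in
    genome assemblies, assembles them into compound microsatellites (CSSRs)
    under a maximum-gap rule, classifies loci as coding or noncoding from
    GFF3 CDS annotation, and computes per-genome and cohort statistics:
    relative abundance and density, cSSR percentage, repeat-type
    composition, per-standard-motif abundance matrices, compound-repeat
    complexity, a Z index of compound-repeat representation, and Pearson
    correlations among genome size, GC content and repeat counts. Includes
    a synthetic-genome generator that plants repeats with exact ground
    truth so the whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
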