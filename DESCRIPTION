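Package: vanscape
Title: Sequence-Specific Anti-Silencing Analysis of Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise sequence-specific anti-silencing of
    transposable elements (TEs) by TE-encoded VANC proteins. Implements
    differential DNA-methylation profiling of TEs from per-cytosine
    bisulfite reports (fractional TE profiles, running 5-cytosine profiles,
    summit-centred metaplots), a count-weighted hypomethylation significance
    statistic, CG differentially-methylated-region (DMR) calling with a
    one-gap merge rule, degenerate (IUPAC) target-motif scanning, typing,
    density/array analysis and discriminative motif discovery, ChIP
    enrichment summaries in fixed genomic bins, DNA and protein dot plots,
    simplified tandem-repeat detection, Poisson-correction distances and
    neighbor-joining phylogenies with bootstrap support. Ships a synthetic
    genome/methylome/ChIP simulator with machine-readable ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
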