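Package: poolrevert
Title: Suppressor Identification from Pooled Revertant Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses "mixture sequencing" suppressor screens in
    haploid yeast: genomic DNA of N revertants of one temperature-sensitive (ts)
    mutant is pooled and sequenced as a single library, so the shared ts anchor
    mutation appears at ~100% allele frequency while each private suppressor
    appears at ~1/N.  Provides a deterministic read simulator (toy genome, gene
    models, parental variants, paired-end reads with a uniform error model), a
    seed-and-extend ungapped aligner with SAM import/export, a pooled variant
    caller testing per-site base counts against a binomial sequencing-error
    null with Bonferroni control, an allele-frequency classifier with
    gene/complex recurrence filtering, and screen-design calculators
    (revertant-frequency window, lane multiplexing, detection power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
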