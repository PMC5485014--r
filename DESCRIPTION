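Package: supergenescan
Title: Differentiation and Diversity Scans for Supergene Regions from
    Haploid Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-recombining supergene regions from two groups of
    haploid genome sequences, in the style of analyses of young sex
    chromosomes. Provides a synthetic-data generator emulating paired
    haploid brothers from social-insect colonies; variant and short tandem
    repeat (STR) filtering; linkage-map based scaffold placement with
    chimera splitting; sliding-window multilocus FST, nucleotide diversity
    and fixed-difference counts on non-N coordinates; Nei-Gojobori (1986)
    synonymous and nonsynonymous divergence between group consensus coding
    sequences; McDonald-Kreitman and related contingency tests; a scan for
    evolutionary strata assessed against a Poisson substitution null; and
    permutation tests of group assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
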