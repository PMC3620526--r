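Package: symbiodiff
Title: Comparative Genomics of Nested Endosymbiont Strain Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiling and strain-pair comparison of highly reduced,
    nested endosymbiont genomes such as the 'Candidatus Tremblaya princeps'
    / 'Moranella endobia' consortium of the citrus mealybug. Reads annotated
    genomes from GenBank flat files, partitions each genome into coding, RNA,
    pseudogene and intergenic fractions, and computes summary statistics
    (GC content by fraction, codon usage and bias tests, stop-codon
    incidence, amino-acid composition ranked by codon GC-richness). Aligns
    near-identical strain pairs with an anchored global aligner, calls and
    left-normalizes substitutions and indels, classifies them by mutational
    class, direction, strand balance and genomic partition, and scores the
    sequence context of indels against homopolymer and microsatellite
    tracts. Estimates dS, dN and omega by the Nei-Gojobori (1986) pathway
    method with Jukes-Cantor correction and bootstrap standard errors,
    detects long exact direct and inverted repeats and inverted-repeat
    flanked regions, and regresses tRNA gene inventories on proteome codon
    demand across genome panels with leave-one-out overload scoring. A
    seeded synthetic-genome simulator plants fully labelled substitutions
    and indels so that every stage is testable against ground truth without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
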