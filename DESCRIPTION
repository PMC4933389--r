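Package: comppop
Title: Comparative Mitochondrial Population Genetics for Co-Occurring Species
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative single-locus (mtDNA) population-genetic analysis for
    sets of co-occurring species: haplotype and nucleotide diversity indexes,
    one-level AMOVA with permutation tests, Nei's gamma-st, Hudson's Snn,
    exact and Monte-Carlo chi-squared tests of haplotype differentiation,
    mismatch distributions with sudden-demographic and spatial-expansion
    fits (tau, parametric-bootstrap confidence intervals, raggedness),
    Tajima's D, Fu's Fs and Ramos-Onsins & Rozas' R2 neutrality tests with
    coalescent null distributions, minimum-spanning haplotype networks, and
    permutational regression/ANOVA with AIC subset selection linking
    reproductive-output traits to genetic variation. Includes a neutral
    coalescent simulator (equilibrium, sudden growth, island migration) so
    every stage is testable on synthetic alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
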