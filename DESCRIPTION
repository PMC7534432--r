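Package: wildintro
Title: Simulation and Detection of Wild-Relative Introgression in Backcross Wheat Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of backcross/single-seed-descent introgression
    populations (hexaploid wheat x Aegilops tauschii style) with a
    pericentromere-suppressed recombination map and optional single-locus
    selection; parent-informed identity-by-descent segment calling from
    biallelic SNP dosages via a three-state hidden-path decoder; and the
    population statistics used to characterise introgression: recombination
    breakpoints and hotspot windows with permutation-overlap enrichment,
    sliding-window nucleotide diversity, parental sequence divergence,
    windowed introgression frequency and efficiency, pericentromeric/distal
    partitioning, and a locus-level selection scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
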