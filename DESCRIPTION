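Package: plastomeSV
Title: Plastome Quadripartite Structure, Repeat-Mediated Rearrangement and
    Conformer Heteroplasmy
Version: 0.1.0
Authors@R:
    person("plastomeSV", "developers", email = "plastomesv@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing structural variation in plastid genomes.
    Detects the quadripartite structure (LSC, SSC and the two inverted
    repeats) of a circular plastome, scans for short direct and inverted
    repeat pairs that can act as recombination substrates, enumerates the
    circular conformers that inverted-repeat-mediated intra- and
    intermolecular recombination can generate (inversion isomers, a dimeric
    intermediate and its two resolution products, including giant
    IR-expanded molecules), predicts the resulting gene gains and losses,
    tests conformer-diagnostic junctions by counting junction-spanning
    reads, and estimates conformer mixture proportions (heteroplasmy) from
    region-wise read depth. Includes a synthetic-data engine that builds toy
    quadripartite genomes with planted repeats, splices conformers
    independently and simulates paired-end reads from conformer mixtures,
    so every analysis step can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
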