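Package: mabcr
Title: Marker-Assisted Backcross Simulation, Selection and Genome-Recovery Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for marker-assisted backcrossing (MABC) programmes that
    introgress a target QTL from a donor into a recurrent parent, modelled on
    SSR-based Saltol introgression in rice. Provides SSR marker-panel
    management and validation, a diploid backcross simulator (Poisson
    crossovers under the Haldane map function, ancestry-segment genomes,
    A/H/B genotype scoring), three-tier foreground/recombinant/background
    selection with fixed-marker dropping across generations,
    recurrent-parent-genome statistics (%A, %R), graphical genotypes,
    frequency histograms, Duncan's multiple-range test for agronomic
    comparisons, and a command-line front end for reproducible campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
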