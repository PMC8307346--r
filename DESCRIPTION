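Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of annotated insect
    mitochondrial genomes: GenBank flat-file input/output, base composition
    and AT/GC strand skew for the canonical genome partitions, codon usage
    and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial code, gene overlap and intergenic spacer geometry,
    control-region tandem-repeat detection, per-gene and sliding-window
    nucleotide diversity, Kimura 2-parameter distances, Nei-Gojobori (1986)
    Ka/Ks, and Bowker matched-pairs symmetry tests. Includes a synthetic
    mitogenome and sequence-evolution simulator with known ground truth so
    every statistic can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    ggplot2,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
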