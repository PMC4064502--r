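Package: matesim
Title: Forward-in-Time Simulation of Social Mating Systems and Genetic
    Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward-in-time population-genetic simulator
    that jointly models social mating rules (monogamy, polygamy, polygyny,
    polyandry, and full/half-sibling inbreeding avoidance) and genetic
    inheritance across autosomal, X-linked, Y-chromosomal and mitochondrial
    loci. DNA is stored bit-packed (32 nucleotides per 64-bit word) and
    mutated under Kimura's two-parameter model; populations evolve under
    piecewise demographic schedules with an optional diversity-targeted
    buffering phase, and a battery of nucleotide-diversity summary
    statistics (segregating sites, Watterson's theta, mean pairwise
    difference, haplotype counts, allelic and per-site heterozygosity) is
    reported for whole demes or samples. Replicate batches are reproducible
    and embarrassingly parallel, suitable as a forward engine for
    simulation-based inference such as Approximate Bayesian Computation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
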