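Package: phosevol
Title: Comparative Analysis of Proline-Directed Phosphosite Density and
    Mammalian Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the density of predicted
    proline-directed ([ST]P) phosphorylation sites in a protein region
    covaries with species maximum lifespan after phylogenetic correction.
    Provides motif scanning and per-species sequence features over an
    alignment-projected C-terminal domain, reference-coordinate mapping and
    strict-identity conservation profiles for multiple sequence alignments,
    phylogenetic generalized least squares under a Brownian-motion
    covariance written from first principles (with an ordinary least
    squares baseline), post-processing of search-engine modified-peptide
    tables into site-level relative phosphopeptide abundances with
    probability filters, and a synthetic-data generator (Yule trees,
    Brownian traits, lifespan-dependent site planting, noisy intensity
    tables) so the whole pipeline can be exercised and calibrated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
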