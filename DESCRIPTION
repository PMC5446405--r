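Package: cgdmd
Title: Coarse-Grained Discrete Molecular Dynamics of Peptide-Protein
    Aggregation and Fibril Metrology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven (discrete) molecular dynamics on step-wise pair
    potentials for coarse-grained models of amyloid peptide aggregation in
    the presence of globular proteins. Builds one-bead-per-residue peptide
    chains, procedural charged globules, and a two-protofibril cross-beta
    fibril model; interactions combine hard cores, hydrophobic square wells
    and a discretized Debye-Hueckel screened Coulomb potential with an
    Anderson thermostat and periodic boundaries. Analysis tools cover
    contact-graph cluster statistics (binding frequencies, per-residue
    binding probabilities, oligomer-size histograms, proteins-per-cluster
    counts), hierarchical clustering of fibril-surface binding poses, and
    worm-like-chain metrology of fibril contours (persistence length by
    bond-correlation, mean-squared end-to-end distance and mean-squared
    midpoint displacement estimators; diameter statistics). Seeded
    synthetic-data generators provide ground-truth inputs for every
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    MASS,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    bio3d,
    Biostrings,
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
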