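Package: oildrop
Title: Fuzzy Oil Drop Analysis of Protein Hydrophobic Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how micelle-like the hydrophobicity distribution of a
    protein structure is. The theoretical distribution places hydrophobicity
    density on each residue from a 3D Gaussian spread over the oriented
    molecule; the observed distribution collects pairwise distance-weighted
    hydrophobic interactions; the two are compared by Kullback-Leibler
    divergence against a uniform reference, yielding the relative distance
    (RD) statistic. Includes fragment selection and residue elimination
    rescoring, per-residue status classification, an early-stage (partially
    unfolded) intermediate model built by projecting backbone dihedrals onto
    an elliptical path in Ramachandran space, backbone reconstruction from
    dihedrals, and a synthetic-structure generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
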