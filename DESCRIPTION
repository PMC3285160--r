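Package: coatmap
Title: Interface Detection and Correlated Evolution in Vesicle Coat Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-protein interfaces in large vesicle
    coat assemblies such as the clathrin lattice. Implements Shrake-Rupley
    solvent-accessible surface area under configurable probe radii,
    interface-residue detection from all-atom structures (buried in the
    complex, exposed in isolation) and from C-alpha-only cryo-EM models via
    calibrated residue-type-dependent cutoffs, near-neighbour decomposition
    of assemblies into subcomplexes, orthologue filtering and per-column
    conservation scoring, and mirror-tree correlation of genetic distance
    matrices with permutation significance. Includes deterministic synthetic
    generators for benchmark complexes and simulated orthologue families.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    seqinr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
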