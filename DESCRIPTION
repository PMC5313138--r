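Package: moblkit
Title: Relaxase Family Discovery, oriT Annotation and DNA Curvature Toolkit
Version: 0.1.0
Authors@R:
    person("Plasmid", "Mobility Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of the in-silico
    pipeline used to delineate a conjugative relaxase family (MOB typing):
    iterative PSSM homology search with empirical Gumbel E-value calibration,
    greedy centroid clustering for redundancy reduction, ZOOPS
    expectation-maximization motif ("signature") discovery and cross-family
    scanning, neighbor-joining phylogenetics with bootstrap and condensed
    trees, translated matching of proteins against circular plasmid databases,
    wedge-model intrinsic DNA curvature profiling of oriT regions (repeats,
    palindromes, GC windows, nic-site localization), and closed-form
    hydrodynamic calculations (Svedberg molar mass, frictional ratio).
    Ground-truth synthetic-data generators make every stage testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
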