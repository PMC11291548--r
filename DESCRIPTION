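Package: pifarch
Title: Domain-Architecture Delimitation of the Molluscan Pif/BMSP Shell
    Matrix Protein Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable in-silico pipeline for delimiting the molluscan
    Pif/BMSP family of shell matrix proteins and characterizing its
    members. Provides Smith-Waterman homology gating of von Willebrand
    factor type A (VWA) domains with Karlin-Altschul E-value calibration,
    tiered classification of chitin-binding (CBM_14-like) domains by
    independent E-value, support-threshold extraction of the family clade
    and its subfamilies from dual-labelled (SH-aLRT/UFBoot) phylogenies,
    delimitation of the variable insert between the two conserved partial
    laminin-G anchor peptides, entropy-based low-complexity-region
    detection with architecture-anchored zone assignment, and amino-acid
    composition clustering by Ward's method with silhouette-guided choice
    of cluster number. A seeded synthetic-family generator with a
    machine-readable truth table makes every stage testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
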