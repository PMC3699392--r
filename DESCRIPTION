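Package: aimpanel
Title: Design and Application of Ancestry-Informative SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing small panels of ancestry-informative SNPs
    (AISNPs) and for inferring continental ancestry and admixture proportions
    with them. Implements Rosenberg's informativeness for assignment (In) and
    pairwise allele-frequency differences (delta), a multi-stage panel-selection
    pipeline (candidate filtering, top-In capping, sliding-window variance-
    inflation-factor LD pruning, top-delta-per-pair selection, iterative
    reduction to multiplex size), Weir-Cockerham FST with permutation tests and
    the Mantel test, maximum-likelihood admixture estimation by EM (supervised
    and unsupervised) with replicate alignment and membership-threshold
    assignment, EIGENSTRAT-style PCA and identity-by-state MDS, and a
    Balding-Nichols simulator of multi-region genotype data with known
    admixture truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
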