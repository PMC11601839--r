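Package: sparsekin
Title: Sparse Ancestry-Adjusted Genetic Relatedness and Mixed-Model
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs a block-diagonal sparse ancestry-adjusted genetic
    relatedness matrix (GRM) from genotype data by separating family
    relatedness from population structure.  Related pairs define pedigree
    blocks; an ancestrally diverse unrelated subset is extracted with a
    greedy algorithm guided by ancestry-divergence scores; ancestry
    principal components are computed with a blocked randomized PCA and
    related subjects are projected onto them; per-subject ancestry-adjusted
    allele frequencies then yield GRM entries only within pedigree blocks.
    The sparse GRM feeds a linear mixed model fitted by average-information
    REML, with genome-wide single-variant score tests calibrated by a
    variance-ratio factor.  A multi-ancestry genotype, pedigree and
    phenotype simulator makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
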