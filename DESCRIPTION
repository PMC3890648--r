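Package: haplopop
Title: Population Genetics of Haploid Multilocus SNP Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of haploid (selfing)
    multilocus SNP genotype panels: locus filtering and multilocus haplotype
    collapsing; gene diversity, percentage of polymorphic loci and rarefaction
    estimators of allelic richness and private allelic richness; hierarchical
    analysis of molecular variance (AMOVA) with permutation significance and
    pairwise F_ST; Mantel tests of isolation by distance and between-region
    comparison of IBD strength; genetic structure inference by principal
    component analysis with Tracy-Widom component selection and Ward
    clustering, by a haploid admixture mixture model fitted with EM, and by
    neighbor-joining trees, including CLUMPP-style alignment of replicate runs
    and cross-method agreement scores; quantitative-trait differentiation
    (Q_ST) from variance components with flowering-trait preprocessing; and
    seeded generators of synthetic genotype, geographic and trait data with
    known truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    geosphere,
    lme4,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, Genetics, Clustering, PrincipalComponents
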