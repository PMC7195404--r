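Package: clinemosaic
Title: Genomic Clines, Ancestry Mosaics, and the Predictability of
    Hybrid Genome Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing patterns of introgression in contemporary
    hybrid zones with the mosaic of ancestry in old or ancient hybrid
    lineages.  Implements expectation-maximization estimation of population
    allele frequencies from genotype likelihoods and designation of
    ancestry-informative markers (AIMs); a correlated-beta Gibbs sampler for
    locus-specific ancestry frequencies in partially stabilized hybrid
    populations; maximum-likelihood hybrid indexes and Bayesian genomic
    clines (alpha, beta) with credible-deviation classification; a
    permutation/randomization framework for x-fold enrichment of locus sets
    (set overlap, Z-chromosome and structural-feature categories, and
    chromosome-size correlations); polarized coupling/repulsion linkage
    disequilibrium, Hudson-style F_ST and a Bayesian pairwise
    isolation-by-distance mixed model with DIC comparison; and
    five-lineage phylogenomic window analyses (exhaustive topology scoring
    over the 15 unrooted trees, topology randomization tests, and f_d
    admixture proportions).  A synthetic-data module generates every input
    the pipeline consumes, with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    vcfR,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
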