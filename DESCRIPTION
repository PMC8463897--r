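Package: meselson
Title: Population-Genomic Tests for the Meselson Effect in Clonal Diploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests multi-individual diploid polymorphism data for the four
    population-genomic signatures of long-term asexual (clonal) evolution
    known as the Meselson effect: (I) within-individual divergence exceeding
    between-population divergence, assessed by multidimensional scaling of
    allele-sharing distances and a hierarchical analysis of molecular
    variance (AMOVA) with a permutation test; (II) an excess of observed
    over Hardy-Weinberg-expected heterozygosity, assessed by per-individual
    inbreeding coefficients, an exact rank-sum comparison, and
    HWE-conditional genotype-profile probabilities on the nonreference site
    frequency spectrum; (III) haplotype rather than population separation at
    the deepest split of per-region haplotype trees, assessed by
    constrained-topology maximum-likelihood fits under JC69, branch-score
    tree distances, and RELL-based approximately unbiased (AU) topology
    tests; and (IV) parallel divergence of the two haplotype subtrees,
    assessed by rooted-topology matching and an exact binomial test. A
    coalescent-style simulator generates clonal and sexual datasets with
    known truth (genotypes, phase blocks, coverage tracks, metadata) so that
    every stage can be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
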