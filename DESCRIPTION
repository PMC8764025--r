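Package: magicmap
Title: Founder Mosaic Reconstruction and QTL Mapping for MAGIC Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-parent advanced-generation
    inter-cross (MAGIC) populations of inbred founders, built around an
    allotetraploid cotton design with eleven founders. Provides a forward
    simulator of the breeding scheme (half-diallel, bulked-pollen random
    mating, single-seed-descent selfing) with planted additive, epistatic
    and polygenic trait architectures; a hidden Markov model that
    reconstructs each recombinant inbred line as a mosaic of
    identity-by-descent founder segments; recombination-bin construction
    and bin-level haplotype GWAS with REML likelihood-ratio tests and
    permutation thresholds; SNP-level mixed-model GWAS with 1/n thresholds
    and LD-aware locus merging; a two-stage pairwise epistasis scan with
    interaction variance partitioning; multi-environment BLUP and
    heritability estimation; SNP functional annotation, LD decay and PCA
    diagnostics; and parental IBD-group functional-allele inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    lme4,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
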