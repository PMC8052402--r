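Package: chromaqtl
Title: Chromatin QTL Mapping, Allelic Imbalance and Colocalisation for
    Multi-Donor Epigenomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative toolkit for mapping genetic effects on chromatin
    phenotypes in multi-donor cohorts: consensus peak construction and
    normalisation of ChIP-seq count matrices (log2 reads-per-million,
    presence filtering, latent-factor correction, quantile normalisation),
    cis quantitative trait locus (QTL) mapping with a single-variance-component
    linear mixed model and two-step multiple-testing control
    (per-feature Bonferroni followed by Storey q-values), LD clumping to
    independent lead variants and proximal/distal classification,
    beta-binomial allele-specific imbalance tests at heterozygous sites,
    pi1-based sharing between molecular layers, promoter-interacting-region
    enrichment via Fisher and genomic permutation tests, and Bayesian
    colocalisation with GWAS traits using Wakefield approximate Bayes factors
    and per-locus maximum-likelihood priors. A synthetic-data generator with
    known ground truth (LD-block genotypes, negative-binomial count
    phenotypes, overdispersed allelic counts, promoter-interaction tables and
    paired locus summary statistics) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
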