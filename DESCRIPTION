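Package: snpher
Title: SNP Heritability of Liability from Case-Control Data and Family-Based Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates narrow-sense heritability of disease liability from
    case-control SNP genotypes by genomic-relationship-matrix restricted
    maximum likelihood (GREML) with principal-component covariates and a
    liability-scale transformation at a stated population prevalence.
    Includes a liability-threshold family simulator with Mendelian
    transmission, rejection-sampling ascertainment of simplex and multiplex
    nuclear families, pseudo-controls assembled from untransmitted parental
    alleles, and an optional assortative-mating rule, used to compute the
    expected heritability attributable to parents, unaffected siblings and
    pseudo-controls under different recruitment designs. Also provides
    genotype quality control (call rates, minor allele frequency,
    Hardy-Weinberg exact test, sex concordance, relatedness), PLINK
    bed/bim/fam and GCTA GRM binary input/output, and tag-SNP genomic
    coverage estimation from linkage-disequilibrium r2 clustering.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
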