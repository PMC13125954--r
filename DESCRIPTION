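Package: hybridotype
Title: Genotype, Ploidy and Ancestry Analysis for Hybridogenetic Water Frogs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of multi-sample SNP data from target-capture
    sequencing of hybridogenetic Pelophylax water frog populations. Implements
    the variant filter chain (biallelic SNPs, no missing data, per-sample depth
    and genotype-quality thresholds, minor allele frequency, one SNP per
    marker), ascertainment of species-diagnostic SNP panels between two
    parental gene pools, per-sample hybrid index and interclass heterozygosity
    (triangle plot coordinates), allele-depth-ratio profiling for parental
    genome dosage (diploid 0.5, triploid 1/3 or 2/3), Gaussian-mixture ploidy
    model selection on allele-balance distributions, supervised and
    unsupervised two-pool ancestry estimation, a sliding-window target-capture
    coverage metric, and a fully parameterized synthetic hybridogenetic cohort
    generator (including the diploid-caller-on-triploid miscall artifact) used
    to validate every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
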