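#!/usr/bin/env Rscript
# Generate the synthetic hybridogenetic study cohort used by all downstream
# analysis scripts: 11 lessonae, 12 ridibundus, 13 diploid esculentus,
# 8 LLR triploids and 1 LRR triploid, 500 markers (~35% diagnostic),
# depth ~ Poisson(40), per-read error 0.005, diploid genotype calling.

library(hybridotype)

out <- "results/fixture"
cfg <- sim_config(seed = 20260920L)
paths <- write_fixture(cfg, out)

tab <- read_vcf(paths[["vcf"]])
truth <- read.table(paths[["truth_samples"]], header = TRUE, sep = "\t")
cat(sprintf("Simulated %d sites x %d samples into %s\n",
            n_sites(tab), length(tab$samples), out))
cat(sprintf("Cohort: %s\n",
            paste(sprintf("%d %s", table(truth$kind),
                          names(table(truth$kind))), collapse = ", ")))
cat(sprintf("Ground truth: %d diploid and %d triploid hybrids\n",
            sum(truth$ploidy == 2 & truth$group == "E"),
            sum(truth$ploidy == 3)))
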