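#!/usr/bin/env Rscript
# Filter the joint VCF (biallelic SNPs, no missing data, DP >= 10,
# GQ >= 20, MAF >= 0.1, one SNP per marker) and ascertain the SNPs that are
# 100% diagnostic between the lessonae and ridibundus parental samples.

library(hybridotype)

tab <- read_vcf("results/fixture/cohort.vcf")
labels <- read_labels("results/fixture/labels.tsv")

filt <- filter_chain(tab)
log <- attr(filt, "filter_log")
cat(sprintf("Filter chain: %d of %d sites pass\n", n_sites(filt), n_sites(tab)))
fails <- table(unlist(strsplit(log$reason[!log$pass], ",")))
for (r in names(fails)) cat(sprintf("  failed %-20s %d\n", r, fails[[r]]))

filt <- thin_one_per_marker(filt)
cat(sprintf("After thinning to one SNP per marker: %d SNPs\n", n_sites(filt)))
write_vcf(filt, "results/filtered.vcf")
write.table(log, "results/filter_log.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

panel <- ascertain_panel(filt, labels)
write_panel(panel, "results/panel.tsv")
cat(sprintf("Diagnostic panel: %d of %d filtered SNPs are fixed differences (ascertained from %d L and %d R samples)\n",
            nrow(panel), n_sites(filt),
            attr(panel, "n_l_samples"), attr(panel, "n_r_samples")))
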