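#!/usr/bin/env Rscript
# Parental genome dosage from allele-depth ratios at diagnostic loci
# (diploid 0.5, triploid 2/3 or 1/3), and ploidy by Gaussian-mixture model
# selection on allele-balance values from all heterozygous-like SNPs.

library(hybridotype)

filt <- read_vcf("results/filtered.vcf")
labels <- read_labels("results/fixture/labels.tsv")
panel <- read_panel("results/panel.tsv")
truth <- read.table("results/fixture/truth_samples.tsv", header = TRUE,
                    sep = "\t")

e_ids <- names(labels)[labels == "E"]
dosage <- dosage_table(filt, panel, e_ids)
write.table(dosage, "results/dosage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Dosage calls among hybrids:\n")
print(table(dosage$call))
profiles <- lapply(e_ids, function(s) ratio_profile(filt, panel, s))
dosage_histogram_plot(profiles, "results/dosage_histograms.pdf")

fits <- list()
for (s in filt$samples) {
  fit <- tryCatch(infer_ploidy(filt, s), error = function(e) NULL)
  if (is.null(fit)) {
    cat(sprintf("  %s: too few heterozygous-like sites for a mixture fit\n", s))
  } else {
    fits[[s]] <- fit
  }
}
df <- ploidy_report(fits, "results/ploidy")
m <- match(df$sample_id, truth$sample_id)
cat(sprintf("Mixture-model ploidy: %d diploid, %d triploid (of %d fitted samples)\n",
            sum(df$best_ploidy == 2), sum(df$best_ploidy == 3), nrow(df)))
cat(sprintf("Agreement with ground-truth ploidy: %d / %d\n",
            sum(df$best_ploidy == truth$ploidy[m]), nrow(df)))
cat(sprintf("Parental samples use fewer informative sites than hybrids (medians %d vs %d)\n",
            median(df$n_sites[truth$group[m] != "E"]),
            median(df$n_sites[truth$group[m] == "E"])))
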