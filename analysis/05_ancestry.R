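#!/usr/bin/env Rscript
# Two-pool ancestry: supervised maximum-likelihood q per sample (closed form
# on the diagnostic panel), an unsupervised K = 2 admixture EM for
# comparison, and the genotype PCA. Also demonstrates the triploid ancestry
# artifact: LLR triploids called as diploids show q_l > 0.5, and the excess
# grows as depth drops.

library(hybridotype)

filt <- read_vcf("results/filtered.vcf")
labels <- read_labels("results/fixture/labels.tsv")
panel <- read_panel("results/panel.tsv")
truth <- read.table("results/fixture/truth_samples.tsv", header = TRUE,
                    sep = "\t")

sup <- do.call(rbind, lapply(filt$samples, function(s) {
  est <- estimate_q_supervised(filt, labels, s, panel = panel)
  data.frame(sample_id = s, q_l = est$q_l, n_loci = est$n_loci)
}))
write.table(sup, "results/ancestry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
m <- match(sup$sample_id, truth$sample_id)
agg <- tapply(sup$q_l, truth$kind[m], mean)
cat("Mean supervised q_l by true kind:\n")
print(round(agg, 4))

uns <- estimate_q_unsupervised(filt, n_replicates = 10, seed = 20260920L,
                               labels = labels)
cat(sprintf("Max |supervised - unsupervised| q: %.4f\n",
            max(abs(sup$q_l - uns$q_l[match(sup$sample_id, uns$sample_id)]))))

pca <- run_pca(filt)
pca_df <- data.frame(sample_id = rownames(pca$coords), pca$coords,
                     group = unname(labels[rownames(pca$coords)]))
write.table(pca_df, "results/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA: PC1 explains %.1f%% of variance and separates L | E | R: group means %s\n",
            100 * pca$var_frac[1],
            paste(sprintf("%s = %.2f", names(tapply(pca_df$PC1, pca_df$group, mean)),
                          tapply(pca_df$PC1, pca_df$group, mean)),
                  collapse = ", ")))

# depth dependence of the triploid artifact, on fresh simulations
excess <- sapply(c(40, 20, 10), function(depth) {
  cfg <- sim_config(n_markers = 300, prop_diagnostic = 1, n_l = 4, n_r = 4,
                    n_e2 = 0, n_e3_llr = 20, n_e3_lrr = 0,
                    mean_depth = depth, seed = 20260920L)
  sim <- simulate_cohort(cfg)
  pan <- truth_panel(sim$truth)
  ids <- sim$truth$samples$sample_id[sim$truth$samples$kind == "E3_LLR"]
  mean(vapply(ids, function(s) {
    estimate_q_supervised(sim$table, sim$labels, s, panel = pan)$q_l
  }, numeric(1))) - 0.5
})
cat(sprintf("Mean excess lessonae ancestry of LLR triploids: %.4f at depth 40, %.4f at 20, %.4f at 10\n",
            excess[1], excess[2], excess[3]))
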