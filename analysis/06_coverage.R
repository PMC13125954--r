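#!/usr/bin/env Rscript
# Target-capture coverage: per marker and sample, the minimum depth of the
# best-covered contiguous 100 bp window (length-independent), summarized
# across the cohort and ranked by summed median coverage.

library(hybridotype)

files <- list.files("results/fixture", pattern = "^depth_.*\\.tsv$",
                    full.names = TRUE)
tracks <- lapply(files, read_depth_table)
names(tracks) <- sub("^depth_(.*)\\.tsv$", "\\1", basename(files))

cov <- summarize_coverage(tracks, window = 100)
write.table(cov$per_marker, "results/coverage_per_marker.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cov$per_sample, "results/coverage_per_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
plot_coverage(cov, "results/coverage.pdf")

cat(sprintf("Coverage over %d markers x %d samples (window 100 bp)\n",
            nrow(cov$matrix), ncol(cov$matrix)))
cat(sprintf("Markers with cross-sample median > %d: %d (%.0f%%); below %d: %d (%.0f%%)\n",
            cov$hi, cov$n_hi, 100 * cov$n_hi / nrow(cov$matrix),
            cov$lo, cov$n_lo, 100 * cov$n_lo / nrow(cov$matrix)))
print(cov$per_sample)
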