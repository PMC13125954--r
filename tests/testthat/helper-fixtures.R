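# Shared in-code fixtures and independent oracles.

# Compact variant_table builder: `gt`, `ad`, `dp`, `gq` given as matrices or
# vectors recycled across samples.
make_table <- function(sites, samples, gt, ad = NULL, dp = 40L, gq = 99L) {
  n <- nrow(sites)
  s <- length(samples)
  fill <- function(x, default) {
    if (is.null(x)) x <- default
    matrix(x, n, s)
  }
  if (is.null(ad)) ad <- "20,20"
  variant_table(sites, fill(gt, "0/1"), fill(ad, "20,20"),
                fill(dp, 40L), fill(gq, 99L), samples)
}

# A 6-record, 10-sample table exercising each filter rule exactly once:
# record 1 indel, 2 low MAF (1/20 = 0.05), 3 a missing genotype, 4 one
# sample at DP 8, 5 one sample at GQ 15, 6 clean. Only record 6 survives.
toy_filter_table <- function() {
  samples <- sprintf("S%02d", 1:10)
  sites <- data.frame(
    marker_id = paste0("m", 1:6), pos = rep(100L, 6),
    ref = c("AT", "A", "C", "G", "T", "A"),
    alt = c("A", "T", "G", "A", "C", "G"),
    stringsAsFactors = FALSE
  )
  het5 <- c(rep("0/1", 5), rep("0/0", 5))   # MAF 0.25
  gt <- rbind(
    het5,
    c("0/1", rep("0/0", 9)),                # MAF 0.05
    c("./.", het5[-1]),
    het5,
    het5,
    het5
  )
  dp <- matrix(40L, 6, 10)
  dp[4, 3] <- 8L
  gq <- matrix(99L, 6, 10)
  gq[5, 7] <- 15L
  variant_table(sites, gt, matrix("20,20", 6, 10), dp, gq, samples)
}

# Noiseless panel-world fixture: `n` diagnostic loci with l_allele = ref,
# plus per-sample genotype strings. AD is set consistently with the
# genotype at high depth.
panel_world <- function(genotypes, n = 100L) {
  samples <- names(genotypes)
  sites <- data.frame(
    marker_id = sprintf("m%04d", seq_len(n)), pos = rep(10L, n),
    ref = rep("A", n), alt = rep("G", n), stringsAsFactors = FALSE
  )
  ad_for <- c("0/0" = "40,0", "0/1" = "20,20", "1/1" = "0,40")
  gt <- vapply(samples, function(s) rep(genotypes[[s]], n), character(n))
  gt <- matrix(gt, n, length(samples))
  ad <- matrix(ad_for[as.vector(gt)], n, length(samples))
  table <- variant_table(sites, gt, ad, matrix(40L, n, length(samples)),
                         matrix(99L, n, length(samples)), samples)
  panel <- structure(
    data.frame(marker_id = sites$marker_id, pos = sites$pos,
               l_allele = "A", r_allele = "G", stringsAsFactors = FALSE),
    class = c("diagnostic_panel", "data.frame")
  )
  list(table = table, panel = panel)
}

# Brute-force oracle for best_window_min: double loop over all windows.
brute_window_min <- function(depths, window) {
  n <- length(depths)
  if (n < window) return(min(depths))
  best <- -Inf
  for (i in seq_len(n - window + 1L)) {
    best <- max(best, min(depths[i:(i + window - 1L)]))
  }
  as.integer(best)
}

# Site key helper for set comparisons.
locus_key <- function(df) paste(df$marker_id, df$pos)
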