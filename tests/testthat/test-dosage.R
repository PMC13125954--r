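test_that("ratios follow allele depths locus by locus", {
  w <- panel_world(list(S = "0/1"), n = 3)
  w$table$ad[, "S"] <- c("10,10", "20,10", "2,0")
  prof <- ratio_profile(w$table, w$panel, "S")
  # l_allele is ref, so r = ref / (ref + alt)
  expect_equal(prof$ratios, c(0.5, 2 / 3, 1))
  expect_equal(prof$n_sites, 3L)
  expect_equal(sum(prof$density), 1)

  # min_total_depth excludes shallow loci
  prof2 <- ratio_profile(w$table, w$panel, "S", min_total_depth = 5)
  expect_equal(prof2$n_sites, 2L)
  expect_error(ratio_profile(w$table, w$panel, "S", min_total_depth = 100),
               "usable depth")
})

test_that("simulated dosage groups have the expected mean ratios", {
  cfg <- sim_config(n_markers = 330, prop_diagnostic = 1,
                    n_l = 4, n_r = 4, n_e2 = 1, n_e3_llr = 1, n_e3_lrr = 1,
                    mean_depth = 40, epsilon = 0.005, seed = 41)
  sim <- simulate_cohort(cfg)
  filt <- filter_chain(sim$table)
  pan <- ascertain_panel(filt, sim$labels)
  expect_gte(nrow(pan), 300)
  m_e2 <- ratio_profile(filt, pan, "E2_01")$mean_ratio
  m_llr <- ratio_profile(filt, pan, "E3_LLR_01")$mean_ratio
  m_lrr <- ratio_profile(filt, pan, "E3_LRR_01")$mean_ratio
  expect_equal(m_e2, 0.5, tolerance = 0.02)
  expect_equal(m_llr, 2 / 3, tolerance = 0.02)
  expect_equal(m_lrr, 1 / 3, tolerance = 0.02)
})

test_that("nearest-centre classification with margin", {
  fake <- function(m, n = 300L) {
    structure(list(sample_id = "x", ratios = rep(m, n), mean_ratio = m,
                   breaks = seq(0, 1, 0.05), density = rep(0.05, 20),
                   n_sites = n),
              class = "allele_ratio_profile")
  }
  expect_equal(classify_dosage(fake(0.51))$call, "diploid")
  expect_equal(classify_dosage(fake(0.65))$call, "triploid_LL_R")
  expect_equal(classify_dosage(fake(0.34))$call, "triploid_L_RR")
  expect_equal(classify_dosage(fake(0.90))$call, "ambiguous")
  expect_equal(classify_dosage(fake(0.58))$call, "ambiguous")
  expect_warning(classify_dosage(fake(0.5, n = 10L)), "only 10 sites")
})

test_that("swapping allele orientation reflects ratios and swaps triploid calls", {
  cfg <- sim_config(n_markers = 200, prop_diagnostic = 1,
                    n_l = 3, n_r = 3, n_e2 = 1, n_e3_llr = 1, n_e3_lrr = 1,
                    seed = 42)
  sim <- simulate_cohort(cfg)
  filt <- filter_chain(sim$table)
  pan <- ascertain_panel(filt, sim$labels)
  swapped <- pan
  swapped$l_allele <- pan$r_allele
  swapped$r_allele <- pan$l_allele
  for (s in c("E2_01", "E3_LLR_01", "E3_LRR_01")) {
    p1 <- ratio_profile(filt, pan, s)
    p2 <- ratio_profile(filt, swapped, s)
    expect_equal(sort(p2$ratios), sort(1 - p1$ratios))
    c1 <- classify_dosage(p1)$call
    c2 <- classify_dosage(p2)$call
    flip <- c(diploid = "diploid", triploid_LL_R = "triploid_L_RR",
              triploid_L_RR = "triploid_LL_R", ambiguous = "ambiguous")
    expect_equal(c2, unname(flip[c1]))
  }
})

test_that("classification is perfect across a noiseless-scale cohort", {
  # 20 individuals per class at depth >= 20 and >= 300 panel loci
  cfg <- sim_config(n_markers = 320, prop_diagnostic = 1,
                    n_l = 3, n_r = 3, n_e2 = 20, n_e3_llr = 20, n_e3_lrr = 20,
                    mean_depth = 20, epsilon = 0, seed = 43)
  sim <- simulate_cohort(cfg)
  pan <- truth_panel(sim$truth)
  truth <- sim$truth$samples
  e_ids <- truth$sample_id[truth$group == "E"]
  calls <- dosage_table(sim$table, pan, e_ids)
  expected <- c(E2 = "diploid", E3_LLR = "triploid_LL_R",
                E3_LRR = "triploid_L_RR")
  m <- match(calls$sample_id, truth$sample_id)
  expect_identical(calls$call, unname(expected[truth$kind[m]]))
})

test_that("dosage histogram plot accepts profiles and rejects none", {
  w <- panel_world(list(S = "0/1"), n = 60)
  prof <- ratio_profile(w$table, w$panel, "S")
  plt <- dosage_histogram_plot(list(prof))
  expect_s3_class(plt, "ggplot")
  expect_error(dosage_histogram_plot(list()), "no profiles")
})
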