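test_that("config validation rejects bad fields", {
  expect_error(sim_config(prop_diagnostic = 1.5))
  expect_error(sim_config(epsilon = 0.7))
  expect_error(sim_config(n_markers = 0))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("cohort composition and ground truth are consistent", {
  cfg <- sim_config(n_markers = 100, n_l = 11, n_r = 12, n_e2 = 13,
                    n_e3_llr = 8, n_e3_lrr = 1, seed = 91)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth$samples
  expect_equal(nrow(truth), 45L)
  expect_equal(sum(truth$kind == "L"), 11L)
  expect_equal(sum(truth$kind == "R"), 12L)
  expect_equal(sum(truth$kind == "E2"), 13L)
  expect_equal(sum(truth$kind == "E3_LLR"), 8L)
  expect_equal(sum(truth$kind == "E3_LRR"), 1L)
  expect_equal(sum(truth$ploidy == 3L), 9L)
  expect_identical(sim$table$samples, truth$sample_id)
  expect_setequal(unique(unname(sim$labels)), c("L", "R", "E"))
  expect_equal(truth$true_q_l[truth$kind == "E3_LLR"][1], 2 / 3)
  expect_equal(nrow(sim$truth$loci), 100L)
})

test_that("the same seed reproduces the cohort and depth tracks exactly", {
  cfg <- sim_config(n_markers = 60, seed = 92)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table$gt, b$table$gt)
  expect_identical(a$table$ad, b$table$ad)
  expect_identical(a$truth, b$truth)
  ta <- simulate_depth_tracks(cfg, sample_ids = "s")
  tb <- simulate_depth_tracks(cfg, sample_ids = "s")
  expect_identical(ta, tb)
  c <- simulate_cohort(sim_config(n_markers = 60, seed = 93))
  expect_false(identical(a$table$ad, c$table$ad))
})

test_that("noiseless deep calls recover diploid genotypes perfectly", {
  cfg <- sim_config(n_markers = 200, n_l = 2, n_r = 2, n_e2 = 2,
                    n_e3_llr = 0, n_e3_lrr = 0, mean_depth = 200,
                    epsilon = 0, seed = 94)
  sim <- simulate_cohort(cfg)
  pan <- truth_panel(sim$truth)
  mp <- hybridotype:::match_panel(sim$table, pan)
  gt_e <- sim$table$gt[mp$row, c("E2_01", "E2_02")]
  expect_true(all(gt_e == "0/1"))
})

test_that("triploid miscalls are homozygous for the double-dose parent and rarer at depth", {
  miscall_rate <- function(depth) {
    cfg <- sim_config(n_markers = 400, prop_diagnostic = 1, n_l = 0, n_r = 0,
                      n_e2 = 0, n_e3_llr = 10, n_e3_lrr = 0,
                      mean_depth = depth, epsilon = 0.005, seed = 95)
    sim <- simulate_cohort(cfg)
    pan <- truth_panel(sim$truth)
    mp <- hybridotype:::match_panel(sim$table, pan)
    gt <- sim$table$gt[mp$row, , drop = FALSE]
    l_hom <- ifelse(mp$l_is_alt, "1/1", "0/0")
    r_hom <- ifelse(mp$l_is_alt, "0/0", "1/1")
    called <- gt != "./."
    list(l = sum(gt == l_hom & called) / sum(called),
         r = sum(gt == r_hom & called) / sum(called))
  }
  m10 <- miscall_rate(10)
  m40 <- miscall_rate(40)
  expect_gt(m10$l, 0.02)          # low depth: visible hom-L miscalls
  expect_gt(m10$l, 10 * m10$r)    # essentially one-directional
  expect_lt(m40$l, m10$l)         # decreasing in depth
})

test_that("a low-error deep AD example is called homozygous L", {
  # dosage 2/3 with all reads from the L allele: the binomial caller
  # prefers hom over het for AD = (12, 0)
  ll_het <- dbinom(0, 12, 0.5, log = TRUE)
  ll_hom <- dbinom(0, 12, 0.005, log = TRUE)
  expect_gt(ll_hom, ll_het)
  call <- hybridotype:::call_diploid(12L, 0L, 0.005)
  expect_equal(call$gt, "0/0")
})

test_that("mean allele ratios converge to the dosage fractions", {
  cfg <- sim_config(n_markers = 600, prop_diagnostic = 1, n_l = 1, n_r = 1,
                    n_e2 = 2, n_e3_llr = 2, n_e3_lrr = 2, mean_depth = 60,
                    epsilon = 0, seed = 96)
  sim <- simulate_cohort(cfg)
  pan <- truth_panel(sim$truth)
  mean_ratio <- function(s) ratio_profile(sim$table, pan, s)$mean_ratio
  expect_equal(mean(sapply(c("E2_01", "E2_02"), mean_ratio)), 0.5,
               tolerance = 0.01)
  expect_equal(mean(sapply(c("E3_LLR_01", "E3_LLR_02"), mean_ratio)), 2 / 3,
               tolerance = 0.01)
  expect_equal(mean(sapply(c("E3_LRR_01", "E3_LRR_02"), mean_ratio)), 1 / 3,
               tolerance = 0.01)
})

test_that("fixture sets are complete, loadable and byte-stable", {
  cfg <- sim_config(n_markers = 40, n_l = 2, n_r = 2, n_e2 = 1,
                    n_e3_llr = 1, n_e3_lrr = 0, seed = 97)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- write_fixture(cfg, dir1)
  p2 <- write_fixture(cfg, dir2)
  tab <- read_vcf(p1[["vcf"]])
  labels <- read_labels(p1[["labels"]])
  expect_identical(tab$samples, names(labels))
  truth <- read.table(p1[["truth_samples"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 6L)
  tracks <- read_depth_table(p1[["depth_L_01"]])
  expect_gt(length(tracks), 0)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), label = nm)
  }
})
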