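test_that("supervised estimates hit the closed form on panel loci", {
  w <- panel_world(list(L1 = "0/0", R1 = "1/1", F1 = "0/1", BX = "0/1"))
  labels <- c(L1 = "L", R1 = "R", F1 = "E", BX = "E")
  # backcross-like: 75 het + 25 hom-L loci -> 175 L alleles of 200
  w$table$gt[76:100, "BX"] <- "0/0"
  q <- function(s) estimate_q_supervised(w$table, labels, s, panel = w$panel)$q_l
  expect_equal(q("F1"), 0.5)
  expect_equal(q("L1"), 1)
  expect_equal(q("R1"), 0)
  expect_equal(q("BX"), 0.625)
  # 100 loci with 75 L alleles of 200 -> 0.375
  w2 <- panel_world(list(L1 = "0/0", R1 = "1/1", S = "0/1"))
  w2$table$gt[76:100, "S"] <- "1/1"
  expect_equal(estimate_q_supervised(w2$table, labels[1:2], "S",
                                     panel = w2$panel)$q_l, 0.375)
})

test_that("supervised general mode agrees with the panel closed form", {
  cfg <- sim_config(n_markers = 300, seed = 71)
  sim <- simulate_cohort(cfg)
  filt <- filter_chain(sim$table)
  pan <- ascertain_panel(filt, sim$labels)
  for (s in c("E2_01", "L_01", "E3_LLR_01")) {
    q_panel <- estimate_q_supervised(filt, sim$labels, s, panel = pan)$q_l
    q_free <- estimate_q_supervised(filt, sim$labels, s)$q_l
    expect_equal(q_free, q_panel, tolerance = 0.03)
  }
})

test_that("diploid calling displaces triploid LLR ancestry toward L, worst at low depth", {
  excess <- function(depth) {
    cfg <- sim_config(n_markers = 300, prop_diagnostic = 1,
                      n_l = 4, n_r = 4, n_e2 = 0, n_e3_llr = 20, n_e3_lrr = 0,
                      mean_depth = depth, epsilon = 0.005, seed = 72)
    sim <- simulate_cohort(cfg)
    pan <- truth_panel(sim$truth)
    ids <- sim$truth$samples$sample_id[sim$truth$samples$kind == "E3_LLR"]
    qs <- vapply(ids, function(s) {
      estimate_q_supervised(sim$table, sim$labels, s, panel = pan)$q_l
    }, numeric(1))
    mean(qs) - 0.5
  }
  e10 <- excess(10)
  e20 <- excess(20)
  e40 <- excess(40)
  expect_gt(e10, 0)
  expect_gt(e10, e20)
  expect_gt(e20, e40)
})

test_that("unsupervised admixture recovers pure and F1 ancestries", {
  cfg <- sim_config(n_markers = 500, prop_diagnostic = 0.35,
                    n_l = 4, n_r = 4, n_e2 = 3, n_e3_llr = 0, n_e3_lrr = 0,
                    seed = 73)
  sim <- simulate_cohort(cfg)
  filt <- filter_chain(sim$table)
  est <- estimate_q_unsupervised(filt, n_replicates = 5, seed = 7,
                                 labels = sim$labels)
  q <- setNames(est$q_l, est$sample_id)
  expect_equal(unname(q[c("L_01", "L_02")]), c(1, 1), tolerance = 0.02)
  expect_equal(unname(q[c("R_01", "R_02")]), c(0, 0), tolerance = 0.02)
  expect_equal(unname(q[c("E2_01", "E2_02", "E2_03")]), rep(0.5, 3),
               tolerance = 0.02)
  # agreement with the supervised estimator
  for (s in c("L_01", "R_01", "E2_01")) {
    sup <- estimate_q_supervised(filt, sim$labels, s)$q_l
    expect_equal(unname(q[s]), sup, tolerance = 0.03)
  }
  expect_error(estimate_q_unsupervised(filt, k = 3), "K = 2")
})

test_that("unsupervised estimation needs at least three samples", {
  w <- panel_world(list(A = "0/1", B = "0/0"), n = 20)
  expect_error(estimate_q_unsupervised(w$table), ">= 3 samples")
})

test_that("PCA separates the three taxa along PC1 with hybrids midway", {
  cfg <- sim_config(n_markers = 300, seed = 74)
  sim <- simulate_cohort(cfg)
  filt <- filter_chain(sim$table)
  pca <- run_pca(filt)
  labels <- sim$labels[rownames(pca$coords)]
  pc1 <- pca$coords[, "PC1"]
  mu <- tapply(pc1, labels, mean)
  # hybrids fall between the parental clusters
  expect_true(mu[["E"]] > min(mu[["L"]], mu[["R"]]) &&
                mu[["E"]] < max(mu[["L"]], mu[["R"]]))
  # cluster separation on PC1: within-group spread far below between-group
  gap <- abs(mu[["L"]] - mu[["R"]])
  spread <- max(tapply(pc1, labels, sd))
  expect_gt(gap, 6 * spread)
  expect_true(all(diff(pca$var_frac) <= 1e-12))
})

test_that("PCA degenerate cases behave", {
  w <- panel_world(list(A = "0/1", B = "0/1", C = "0/0"), n = 10)
  # identical samples A and B get identical coordinates
  pca <- run_pca(w$table)
  expect_equal(pca$coords["A", ], pca$coords["B", ])
  # constant matrix is an error
  w2 <- panel_world(list(A = "0/1", B = "0/1"), n = 5)
  expect_error(run_pca(w2$table), "monomorphic or constant")
  # single polymorphic locus: PC1 carries all variance
  w3 <- panel_world(list(A = "0/0", B = "1/1"), n = 1)
  pca3 <- run_pca(w3$table, n_components = 1)
  expect_equal(pca3$var_frac[1], 1)
})
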