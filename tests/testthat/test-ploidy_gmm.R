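test_that("site selection applies depth, balance and quality rules", {
  sites <- data.frame(marker_id = paste0("m", 1:4), pos = 10L,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  tab <- make_table(sites, "S", gt = "0/1",
                    ad = c("30,30", "58,2", "12,6", "25,25"),
                    dp = 60L, gq = c(90L, 90L, 90L, 10L))
  vals <- select_sites(tab, "S", min_sites = 1L)
  # kept: only 30,30 (58,2 fails balance bounds, 12,6 fails depth,
  # 25,25 fails the quality knob)
  expect_equal(vals, 0.5)
  vals2 <- select_sites(tab, "S", min_sites = 1L, gq_min = 0L)
  expect_equal(sort(vals2), c(0.5, 0.5))
  expect_error(select_sites(tab, "S", min_sites = 100L), "only \\d+ usable")
})

test_that("denoise estimates the uniform noise fraction", {
  clean <- withr::with_seed(51, pmin(pmax(rnorm(600, 0.5, 0.05), 0.01), 0.99))
  dn <- denoise(clean)
  expect_lt(dn$noise_fraction, 0.05)
  expect_true(all(dn$weights >= 0 & dn$weights <= 1))

  mixed <- withr::with_seed(52, c(runif(300), rnorm(300, 0.5, 0.05)))
  mixed <- pmin(pmax(mixed, 0.01), 0.99)
  dn2 <- denoise(mixed)
  expect_lt(abs(dn2$noise_fraction - 0.5), 0.1)
  expect_error(denoise(clean[1:50]), "minimum 100")
})

test_that("mixture log-likelihood matches a brute-force recomputation", {
  vals <- withr::with_seed(53, c(rnorm(200, 1 / 3, 0.06), rnorm(220, 2 / 3, 0.06)))
  vals <- pmin(pmax(vals, 0.01), 0.99)
  w <- withr::with_seed(54, runif(length(vals), 0.5, 1))
  fit <- fit_ploidy_models(vals, weights = w)
  for (nm in names(fit$fixed_fits)) {
    f <- fit$fixed_fits[[nm]]
    brute <- sum(w * log(rowSums(sapply(seq_along(f$means), function(j) {
      f$weights[j] * dnorm(vals, f$means[j], sqrt(f$var))
    }))))
    expect_equal(f$loglik, brute, tolerance = 1e-8)
    expect_equal(fit$loglik_fixed[[nm]], f$loglik)
  }
  fr <- fit$free_fit
  brute_free <- sum(w * log(rowSums(sapply(1:3, function(j) {
    fr$weights[j] * dnorm(vals, fr$means[j], sqrt(fr$var))
  }))))
  expect_equal(fit$loglik_free, brute_free, tolerance = 1e-8)
})

test_that("the free model never fits worse than a fixed model", {
  gen <- list(
    diploid = function() rnorm(400, 0.5, 0.05),
    triploid = function() c(rnorm(200, 1 / 3, 0.05), rnorm(200, 2 / 3, 0.05)),
    flat = function() runif(400, 0.15, 0.85)
  )
  for (i in seq_along(gen)) {
    vals <- withr::with_seed(60 + i, pmin(pmax(gen[[i]](), 0.01), 0.99))
    fit <- fit_ploidy_models(vals)
    expect_true(all(fit$delta >= -1e-6))
  }
})

test_that("generative ploidy is recovered on clean mixtures", {
  vals2 <- withr::with_seed(55, pmin(pmax(rnorm(500, 0.5, 0.05), 0.01), 0.99))
  expect_equal(fit_ploidy_models(vals2)$best_ploidy, 2L)
  vals3 <- withr::with_seed(56, pmin(pmax(c(rnorm(250, 1 / 3, 0.05),
                                            rnorm(250, 2 / 3, 0.05)), 0.01), 0.99))
  expect_equal(fit_ploidy_models(vals3)$best_ploidy, 3L)
  # degenerate input: all values identical -> variance floor, diploid wins
  fit0 <- suppressWarnings(fit_ploidy_models(rep(0.5, 200)))
  expect_equal(fit0$best_ploidy, 2L)
  expect_lt(fit0$delta[["2"]], 1e-6)
  expect_true(0 <= fit0$r_squared && fit0$r_squared <= 1)
})

test_that("end-to-end ploidy inference works on simulated samples", {
  cfg <- sim_config(n_markers = 400, prop_diagnostic = 1,
                    n_l = 0, n_r = 0, n_e2 = 1, n_e3_llr = 1, n_e3_lrr = 0,
                    mean_depth = 40, seed = 57)
  sim <- simulate_cohort(cfg)
  f2 <- infer_ploidy(sim$table, "E2_01")
  f3 <- infer_ploidy(sim$table, "E3_LLR_01")
  expect_equal(f2$best_ploidy, 2L)
  expect_equal(f3$best_ploidy, 3L)
  expect_gte(f2$n_sites, 300)
  expect_true(f2$noise_fraction >= 0 && f2$noise_fraction < 1)
  expect_true(f2$r_squared >= 0 && f2$r_squared <= 1)
})

test_that("parental samples still fit when enough heterozygous sites exist", {
  cfg <- sim_config(n_markers = 600, prop_diagnostic = 0.35,
                    n_l = 1, n_r = 1, n_e2 = 1, n_e3_llr = 0, n_e3_lrr = 0,
                    seed = 58)
  sim <- simulate_cohort(cfg)
  v_par <- select_sites(sim$table, "L_01", min_sites = 50L)
  v_hyb <- select_sites(sim$table, "E2_01", min_sites = 50L)
  expect_lt(length(v_par), length(v_hyb) / 2)  # parentals are less heterozygous
  fit <- infer_ploidy(sim$table, "L_01", min_sites = 50L)
  expect_equal(fit$best_ploidy, 2L)
})

test_that("the ploidy report summarizes a mixed cohort", {
  cfg <- sim_config(n_markers = 350, prop_diagnostic = 1,
                    n_l = 0, n_r = 0, n_e2 = 3, n_e3_llr = 2, n_e3_lrr = 1,
                    seed = 59)
  sim <- simulate_cohort(cfg)
  fits <- lapply(sim$table$samples, function(s) infer_ploidy(sim$table, s))
  prefix <- file.path(withr::local_tempdir(), "ploidy")
  df <- ploidy_report(fits, prefix)
  expect_true(file.exists(paste0(prefix, ".tsv")))
  expect_equal(sum(df$best_ploidy == 2L), 3L)
  expect_equal(sum(df$best_ploidy == 3L), 3L)
  expect_error(ploidy_report(list(), prefix), "no ploidy fits")
})
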