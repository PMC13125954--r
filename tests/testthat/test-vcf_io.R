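test_that("write/read round trip preserves every consumed field", {
  cfg <- sim_config(n_markers = 50, n_l = 2, n_r = 2, n_e2 = 1,
                    n_e3_llr = 1, n_e3_lrr = 0, seed = 11)
  tab <- simulate_cohort(cfg)$table
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tab, path)
  back <- read_vcf(path)
  expect_identical(back$sites, tab$sites)
  expect_identical(back$gt, tab$gt)
  expect_identical(back$ad, tab$ad)
  expect_identical(back$dp, tab$dp)
  expect_identical(back$gq, tab$gq)
  expect_identical(back$samples, tab$samples)
})

test_that("triploid genotype strings survive a round trip", {
  cfg <- sim_config(n_markers = 20, n_l = 1, n_r = 1, n_e2 = 0,
                    n_e3_llr = 1, n_e3_lrr = 1, emit_true_gt = TRUE,
                    seed = 12)
  tab <- simulate_cohort(cfg)$table
  expect_true(any(grepl("^[01](/[01]){2}$", tab$gt[, "E3_LLR_01"])))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tab, path)
  expect_identical(read_vcf(path)$gt, tab$gt)
})

test_that("empty tables round trip as header-only VCF", {
  empty <- variant_table(
    data.frame(marker_id = character(0), pos = integer(0),
               ref = character(0), alt = character(0)),
    matrix(character(0), 0, 2), matrix(character(0), 0, 2),
    matrix(integer(0), 0, 2), matrix(integer(0), 0, 2), c("a", "b")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, path)
  back <- read_vcf(path)
  expect_equal(n_sites(back), 0L)
  expect_identical(back$samples, c("a", "b"))
})

test_that("missing genotypes and missing AD are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "m1\t10\t.\tA\tG\t.\t.\t.\tGT:AD:DP:GQ\t./.:.:.:.\t0/1:5,6:11:50"
  ), path)
  tab <- read_vcf(path)
  expect_identical(tab$gt[1, ], c(s1 = "./.", s2 = "0/1"))
  expect_true(is.na(tab$dp[1, "s1"]))
  expect_identical(tab$dp[1, "s2"], c(s2 = 11L))

  no_ad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "m1\t10\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1"
  ), no_ad)
  expect_error(read_vcf(no_ad), "AD")
})

test_that("filter chain applies each rule and keeps only the clean record", {
  tab <- toy_filter_table()
  out <- filter_chain(tab)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$sites$marker_id, "m6")
  log <- attr(out, "filter_log")
  expect_equal(log$pass, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_match(log$reason[1], "not_biallelic_snp")
  expect_match(log$reason[2], "maf")
  expect_match(log$reason[3], "missing_genotype")
  expect_match(log$reason[4], "dp_lt_10")
  expect_match(log$reason[5], "gq_lt_20")
})

test_that("filter chain is idempotent and a clean table passes unchanged", {
  cfg <- sim_config(n_markers = 120, seed = 13)
  tab <- simulate_cohort(cfg)$table
  once <- filter_chain(tab)
  twice <- filter_chain(once)
  expect_identical(once$sites, twice$sites)
  expect_identical(once$gt, twice$gt)
  expect_true(all(attr(twice, "filter_log")$pass))
})

test_that("maf_min = 0 disables only the MAF rule", {
  tab <- toy_filter_table()
  out <- filter_chain(tab, maf_min = 0)
  expect_setequal(out$sites$marker_id, c("m2", "m6"))
})

test_that("thinning keeps the first SNP per marker in position order", {
  sites <- data.frame(
    marker_id = c("mA", "mA", "mA", "mB"),
    pos = c(200L, 10L, 50L, 30L),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  tab <- make_table(sites, c("s1", "s2"), gt = "0/1")
  thin <- thin_one_per_marker(tab)
  expect_equal(nrow(thin$sites), 2L)
  expect_equal(thin$sites$pos[thin$sites$marker_id == "mA"], 10L)
  # idempotent on already-thin tables
  expect_identical(thin_one_per_marker(thin)$sites, thin$sites)
})

test_that("thinning yields one record per distinct marker on multi-SNP data", {
  cfg <- sim_config(n_markers = 60, snps_per_marker = 4, seed = 14)
  tab <- simulate_cohort(cfg)$table
  thin <- thin_one_per_marker(tab)
  expect_equal(n_sites(thin), length(unique(tab$sites$marker_id)))
  expect_false(any(duplicated(thin$sites$marker_id)))
})
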