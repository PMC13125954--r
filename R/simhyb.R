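#' Configuration for the synthetic hybridogenetic cohort
#'
#' Parameterizes a two-pool hybridogenetic population and its sequencing:
#' two fixed parental gene pools (lessonae L and ridibundus R), diploid F1
#' hybrids (`E2`, one genome of each), triploids with a 2:1 parental genome
#' dosage (`E3_LLR`, `E3_LRR`), depth-dependent allele-depth sampling with a
#' symmetric per-read error, and a diploid genotype caller applied to every
#' sample — including triploids, whose heterozygous sites are then
#' occasionally miscalled homozygous for the double-dose parent.
#'
#' Defaults mirror the study system this generator emulates: a cohort of
#' 11 L, 12 R, 13 diploid and 8+1 triploid hybrids, ~35% of SNPs fixed
#' between the pools, and mean site depth 40.
#'
#' @param n_markers number of target markers (default 500).
#' @param snps_per_marker SNPs simulated per marker (default 1; the thinning
#'   step is exercised when > 1).
#' @param prop_diagnostic fraction of SNPs generated as fixed differences
#'   between the pools (default 0.35).
#' @param beta_shape length-2 Beta shape for the shared-polymorphism allele
#'   frequency of non-diagnostic SNPs (default `c(2, 2)`).
#' @param n_l,n_r,n_e2,n_e3_llr,n_e3_lrr cohort composition (defaults 11,
#'   12, 13, 8, 1).
#' @param mean_depth mean sequencing depth per site (default 40).
#' @param depth_model `"poisson"` (default) or `"nbinom"`.
#' @param nb_size negative-binomial size (dispersion) when
#'   `depth_model = "nbinom"` (default 10).
#' @param epsilon symmetric per-read sequencing error (default 0.005).
#' @param emit_true_gt emit true (possibly 3-allele) genotypes instead of
#'   the diploid caller's output; for round-trip tests only (default FALSE).
#' @param marker_len_range min/max marker length for depth tracks
#'   (default `c(100, 1000)`).
#' @param track_smooth moving-average window for depth-track autocorrelation
#'   (default 25 bases).
#' @param prop_failed_markers fraction of markers with near-zero capture
#'   efficiency in the depth tracks (default 0.3).
#' @param efficiency_sdlog log-normal sd of per-marker capture efficiency
#'   (default 0.6).
#' @param seed RNG seed (mandatory for reproducibility; default 1).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_markers = 500L, snps_per_marker = 1L,
                       prop_diagnostic = 0.35, beta_shape = c(2, 2),
                       n_l = 11L, n_r = 12L, n_e2 = 13L,
                       n_e3_llr = 8L, n_e3_lrr = 1L,
                       mean_depth = 40, depth_model = c("poisson", "nbinom"),
                       nb_size = 10, epsilon = 0.005,
                       emit_true_gt = FALSE,
                       marker_len_range = c(100L, 1000L),
                       track_smooth = 25L, prop_failed_markers = 0.3,
                       efficiency_sdlog = 0.6, seed = 1L) {
  depth_model <- match.arg(depth_model)
  cfg <- list(
    n_markers = as.integer(n_markers), snps_per_marker = as.integer(snps_per_marker),
    prop_diagnostic = prop_diagnostic, beta_shape = beta_shape,
    n_l = as.integer(n_l), n_r = as.integer(n_r), n_e2 = as.integer(n_e2),
    n_e3_llr = as.integer(n_e3_llr), n_e3_lrr = as.integer(n_e3_lrr),
    mean_depth = mean_depth, depth_model = depth_model, nb_size = nb_size,
    epsilon = epsilon, emit_true_gt = isTRUE(emit_true_gt),
    marker_len_range = as.integer(marker_len_range),
    track_smooth = as.integer(track_smooth),
    prop_failed_markers = prop_failed_markers,
    efficiency_sdlog = efficiency_sdlog,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_markers >= 1L, cfg$snps_per_marker >= 1L,
    cfg$prop_diagnostic >= 0, cfg$prop_diagnostic <= 1,
    length(cfg$beta_shape) == 2L, all(cfg$beta_shape > 0),
    cfg$n_l >= 0L, cfg$n_r >= 0L, cfg$n_e2 >= 0L,
    cfg$n_e3_llr >= 0L, cfg$n_e3_lrr >= 0L,
    cfg$mean_depth > 0, cfg$epsilon >= 0, cfg$epsilon < 0.5,
    cfg$prop_failed_markers >= 0, cfg$prop_failed_markers <= 1,
    length(cfg$seed) == 1L, !is.na(cfg$seed)
  )
  structure(cfg, class = "sim_config")
}

# sample kinds and their genome composition (copies drawn from each pool)
kind_copies <- list(
  L = c(l = 2L, r = 0L), R = c(l = 0L, r = 2L),
  E2 = c(l = 1L, r = 1L), E3_LLR = c(l = 2L, r = 1L), E3_LRR = c(l = 1L, r = 2L)
)

# Diploid genotype caller on (ref_reads, alt_reads): argmax binomial
# likelihood over hom-ref / het / hom-alt with error eps; GQ is the
# phred-scaled best/second-best likelihood ratio, capped at 99.
call_diploid <- function(ref_reads, alt_reads, eps) {
  eps <- max(eps, 1e-6)
  n <- ref_reads + alt_reads
  ll <- cbind(
    dbinom(alt_reads, n, eps, log = TRUE),
    dbinom(alt_reads, n, 0.5, log = TRUE),
    dbinom(alt_reads, n, 1 - eps, log = TRUE)
  )
  best <- max.col(ll, ties.method = "first")
  second <- vapply(seq_along(best), function(i) max(ll[i, -best[i]]), numeric(1))
  gq <- pmin(99L, as.integer(round(10 / log(10) * (ll[cbind(seq_along(best), best)] - second))))
  gt <- c("0/0", "0/1", "1/1")[best]
  missing <- n == 0L
  gt[missing] <- "./."
  gq[missing] <- 0L
  list(gt = gt, gq = gq)
}

#' Simulate a hybridogenetic cohort
#'
#' Generates, per sample and site: the true genotype from the sample's
#' genome composition, a total depth from the depth model, an L-supporting
#' read count `Binomial(depth, f (1 - eps) + (1 - f) eps)` where `f` is the
#' sample's allelic dosage fraction at the site, and a diploid genotype call
#' (maximum binomial likelihood over hom-ref/het/hom-alt) with a
#' phred-scaled GQ. The emitted GT is the diploid caller's output unless
#' `emit_true_gt` is set.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [variant_table()]), `labels` (named group
#'   vector; hybrids are `E`), and `truth` (list of `loci` and `samples`
#'   data.frames carrying the diagnostic flags, allele orientations, true
#'   ploidy, L-genome dosage and ancestry of every sample).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_loci <- config$n_markers * config$snps_per_marker
    marker_id <- rep(sprintf("marker_%05d", seq_len(config$n_markers)),
                     each = config$snps_per_marker)
    pos <- if (config$snps_per_marker == 1L) {
      rep(50L, n_loci)
    } else {
      as.integer(unlist(lapply(seq_len(config$n_markers), function(i) {
        sort(sample.int(950L, config$snps_per_marker)) + 10L
      })))
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_loci, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

    n_diag <- round(config$prop_diagnostic * n_loci)
    is_diag <- rep(FALSE, n_loci)
    is_diag[sample.int(n_loci, n_diag)] <- TRUE
    # alt-allele frequency in each pool
    l_is_alt <- rep(NA, n_loci)
    l_is_alt[is_diag] <- runif(n_diag) < 0.5
    shared <- rbeta(n_loci, config$beta_shape[1], config$beta_shape[2])
    p_alt_l <- ifelse(is_diag, as.numeric(l_is_alt), shared)
    p_alt_r <- ifelse(is_diag, 1 - as.numeric(l_is_alt), shared)

    kinds <- rep(names(kind_copies),
                 times = c(config$n_l, config$n_r, config$n_e2,
                           config$n_e3_llr, config$n_e3_lrr))
    if (length(kinds) == 0L) stop("empty cohort")
    # stable, readable ids: kind plus within-kind index in cohort order
    sample_ids <- character(length(kinds))
    counter <- integer(0)
    for (i in seq_along(kinds)) {
      counter[kinds[i]] <- (if (is.na(counter[kinds[i]])) 0L else counter[kinds[i]]) + 1L
      sample_ids[i] <- sprintf("%s_%02d", kinds[i], counter[kinds[i]])
    }

    gt <- ad <- matrix("", n_loci, length(kinds))
    dp <- gq <- matrix(0L, n_loci, length(kinds))
    true_alt_copies <- matrix(0L, n_loci, length(kinds))
    for (i in seq_along(kinds)) {
      cp <- kind_copies[[kinds[i]]]
      m_tot <- sum(cp)
      alt_copies <- rbinom(n_loci, cp[["l"]], p_alt_l) +
        rbinom(n_loci, cp[["r"]], p_alt_r)
      true_alt_copies[, i] <- alt_copies
      f_alt <- alt_copies / m_tot
      depth <- switch(config$depth_model,
        poisson = rpois(n_loci, config$mean_depth),
        nbinom = rnbinom(n_loci, size = config$nb_size, mu = config$mean_depth)
      )
      p_read_alt <- f_alt * (1 - config$epsilon) + (1 - f_alt) * config$epsilon
      alt_reads <- rbinom(n_loci, depth, p_read_alt)
      ref_reads <- depth - alt_reads
      if (config$emit_true_gt) {
        gt[, i] <- vapply(seq_len(n_loci), function(j) {
          paste(sort(c(rep(0L, m_tot - alt_copies[j]), rep(1L, alt_copies[j]))),
                collapse = "/")
        }, character(1))
        gt[depth == 0L, i] <- paste(rep(".", m_tot), collapse = "/")
        gq[, i] <- 99L
      } else {
        call <- call_diploid(ref_reads, alt_reads, config$epsilon)
        gt[, i] <- call$gt
        gq[, i] <- call$gq
      }
      ad[, i] <- paste(ref_reads, alt_reads, sep = ",")
      dp[, i] <- depth
    }

    sites <- data.frame(marker_id = marker_id, pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
    table <- variant_table(sites, gt, ad, dp, gq, sample_ids)
    group <- c(L = "L", R = "R", E2 = "E", E3_LLR = "E", E3_LRR = "E")[kinds]
    labels <- setNames(unname(group), sample_ids)
    ploidy <- vapply(kinds, function(k) sum(kind_copies[[k]]), integer(1))
    l_copies <- vapply(kinds, function(k) kind_copies[[k]][["l"]], integer(1))
    truth <- list(
      loci = data.frame(
        marker_id = marker_id, pos = pos, is_diagnostic = is_diag,
        l_allele = ifelse(is_diag, ifelse(l_is_alt, alt, ref), NA_character_),
        r_allele = ifelse(is_diag, ifelse(l_is_alt, ref, alt), NA_character_),
        p_alt_l = p_alt_l, p_alt_r = p_alt_r,
        stringsAsFactors = FALSE
      ),
      samples = data.frame(
        sample_id = sample_ids, group = unname(group), kind = kinds,
        ploidy = unname(ploidy), l_copies = unname(l_copies),
        true_q_l = unname(l_copies / ploidy),
        stringsAsFactors = FALSE
      )
    )
    list(table = table, labels = labels, truth = truth)
  })
}

#' Ground-truth diagnostic panel of a simulated cohort
#'
#' @param truth the `truth` element returned by [simulate_cohort()].
#' @return a `diagnostic_panel` of the loci generated as fixed differences.
#' @export
truth_panel <- function(truth) {
  loci <- truth$loci[truth$loci$is_diagnostic, , drop = FALSE]
  structure(
    data.frame(marker_id = loci$marker_id, pos = loci$pos,
               l_allele = loci$l_allele, r_allele = loci$r_allele,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("diagnostic_panel", "data.frame")
  )
}

#' Simulate autocorrelated per-base depth tracks
#'
#' One track per marker per sample: Poisson counts at rate
#' `mean_depth x efficiency` smoothed by a moving average of width
#' `track_smooth`. A `prop_failed_markers` fraction of markers gets
#' near-zero capture efficiency; per-marker efficiencies are recorded in the
#' `"efficiency"` attribute.
#'
#' @param config a [sim_config()].
#' @param sample_ids sample names for the tracks (default `track_01..04`).
#' @return named list (per sample) of named lists (per marker) of integer
#'   depth vectors, with attributes `efficiency` (named numeric) and
#'   `lengths`.
#' @export
simulate_depth_tracks <- function(config, sample_ids = sprintf("track_%02d", 1:4)) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 7919L, {
    markers <- sprintf("marker_%05d", seq_len(config$n_markers))
    lens <- sample(seq(config$marker_len_range[1], config$marker_len_range[2]),
                   config$n_markers, replace = TRUE)
    failed <- runif(config$n_markers) < config$prop_failed_markers
    eff <- ifelse(failed, runif(config$n_markers, 0, 0.02),
                  rlnorm(config$n_markers, meanlog = 0,
                         sdlog = config$efficiency_sdlog))
    names(eff) <- markers
    smooth <- max(1L, config$track_smooth)
    out <- lapply(sample_ids, function(s) {
      tr <- lapply(seq_along(markers), function(j) {
        raw <- rpois(lens[j], config$mean_depth * eff[j])
        if (smooth > 1L && lens[j] > smooth) {
          k <- rep(1 / smooth, smooth)
          sm <- stats::filter(raw, k, sides = 2)
          sm[is.na(sm)] <- raw[is.na(sm)]
          as.integer(round(sm))
        } else {
          as.integer(raw)
        }
      })
      names(tr) <- markers
      tr
    })
    names(out) <- sample_ids
    attr(out, "efficiency") <- eff
    attr(out, "lengths") <- setNames(lens, markers)
    out
  })
}

#' Write a complete self-consistent fixture set
#'
#' VCF + labels + ground-truth tables + per-sample depth tables + config
#' echo, all plain text, all loadable by the analysis modules. Re-running
#' with the same config produces byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named vector of the paths written.
#' @export
write_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  tracks <- simulate_depth_tracks(config,
                                  sample_ids = head(sim$table$samples, 4))
  paths <- c(
    vcf = file.path(out_dir, "cohort.vcf"),
    labels = file.path(out_dir, "labels.tsv"),
    truth_loci = file.path(out_dir, "truth_loci.tsv"),
    truth_samples = file.path(out_dir, "truth_samples.tsv"),
    config = file.path(out_dir, "config.yaml"),
    readme = file.path(out_dir, "README.txt")
  )
  write_vcf(sim$table, paths[["vcf"]])
  write_labels(sim$labels, paths[["labels"]])
  write.table(sim$truth$loci, paths[["truth_loci"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$samples, paths[["truth_samples"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(tracks)) {
    p <- file.path(out_dir, sprintf("depth_%s.tsv", s))
    write_depth_table(tracks[[s]], p)
    paths[[paste0("depth_", s)]] <- p
  }
  yaml::write_yaml(unclass(config), paths[["config"]])
  writeLines(c(
    "Synthetic hybridogenetic cohort fixture",
    "",
    "cohort.vcf          multi-sample VCF (GT:AD:DP:GQ), diploid-called",
    "labels.tsv          sample_id <TAB> group (L/R/E)",
    "truth_loci.tsv      per-locus ground truth (diagnostic flag, alleles)",
    "truth_samples.tsv   per-sample ground truth (ploidy, dosage, q_l)",
    "depth_<sample>.tsv  per-base depth tracks (marker, pos, depth)",
    "config.yaml         full generator configuration (incl. seed)"
  ), con = paths[["readme"]])
  invisible(paths)
}
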