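#' Pipeline configuration
#'
#' Bundles the input paths (or a simulation config), every module threshold
#' and the stages to run for [run_pipeline()]. Thresholds default to the
#' values used throughout the analyses: MAF 0.1, per-sample depth 10 and
#' genotype quality 20 in the filter chain, summed depth 20 for
#' allele-balance site selection, and a 100 bp coverage window.
#'
#' @param out_dir output directory.
#' @param vcf,labels,depth_dir optional input paths; when `vcf` is NULL the
#'   `simulate` stage generates the cohort from `sim`.
#' @param sim a [sim_config()] used by the `simulate` stage.
#' @param stages character vector of stages to run, among
#'   `simulate, filter, panel, triangle, dosage, ploidy, ancestry, coverage,
#'   report`.
#' @param maf_min,dp_min,gq_min filter-chain thresholds.
#' @param min_total_depth minimum summed L+R depth for dosage ratios.
#' @param margin dosage nearest-centre ambiguity margin.
#' @param gmm_min_depth,ratio_bounds,gmm_min_sites allele-balance site
#'   selection for ploidy fitting.
#' @param window coverage window length (bases).
#' @param seed seed for every stochastic stage.
#' @param plots draw plots (best-effort; failures warn, default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, vcf = NULL, labels = NULL,
                            depth_dir = NULL, sim = sim_config(),
                            stages = c("simulate", "filter", "panel",
                                       "triangle", "dosage", "ploidy",
                                       "ancestry", "coverage", "report"),
                            maf_min = 0.1, dp_min = 10L, gq_min = 20L,
                            min_total_depth = 1L, margin = 0.07,
                            gmm_min_depth = 20L, ratio_bounds = c(0.1, 0.9),
                            gmm_min_sites = 100L, window = 100L,
                            seed = 1L, plots = TRUE) {
  known <- c("simulate", "filter", "panel", "triangle", "dosage", "ploidy",
             "ancestry", "coverage", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(maf_min >= 0, maf_min < 1, dp_min >= 0, gq_min >= 0,
            min_total_depth >= 1, margin > 0, margin < 0.5,
            length(ratio_bounds) == 2L, ratio_bounds[1] < ratio_bounds[2],
            window >= 1)
  structure(
    list(out_dir = out_dir, vcf = vcf, labels = labels, depth_dir = depth_dir,
         sim = sim, stages = stages, maf_min = maf_min, dp_min = dp_min,
         gq_min = gq_min, min_total_depth = min_total_depth, margin = margin,
         gmm_min_depth = gmm_min_depth, ratio_bounds = ratio_bounds,
         gmm_min_sites = gmm_min_sites, window = window,
         seed = as.integer(seed), plots = isTRUE(plots)),
    class = "pipeline_config"
  )
}

# Plots never fail the pipeline.
try_plot <- function(expr, what) {
  tryCatch(expr, error = function(e) {
    warning("plot '", what, "' failed: ", conditionMessage(e))
    NULL
  })
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate/load, filter + thin, panel, triangle, dosage, ploidy, ancestry,
#' coverage, report), writing one TSV per stage into `out_dir` plus a log of
#' the effective configuration. The combined per-sample report juxtaposes
#' the triangle coordinates, dosage call, mixture-model ploidy and ancestry
#' fraction, and flags samples whose dosage call and mixture ploidy
#' disagree. Two runs with the same configuration produce identical tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(stage, dep, have) {
    if (stage %in% stages && !dep %in% stages && !have) {
      stop("stage '", stage, "' requires stage '", dep,
           "' (or a corresponding input file)")
    }
  }
  need("filter", "simulate", !is.null(config$vcf))
  for (s in c("panel", "triangle", "dosage", "ploidy", "ancestry")) {
    need(s, "filter", FALSE)
  }
  need("triangle", "panel", FALSE)
  need("dosage", "panel", FALSE)
  need("coverage", "simulate", !is.null(config$depth_dir))

  cfg_echo <- unclass(config)
  cfg_echo$sim <- unclass(cfg_echo$sim)
  yaml::write_yaml(cfg_echo, file.path(config$out_dir, "pipeline_log.yaml"))

  res <- list()
  out <- function(name) file.path(config$out_dir, name)
  sim_cfg <- config$sim
  sim_cfg$seed <- config$seed
  tracks <- NULL

  if ("simulate" %in% stages && is.null(config$vcf)) {
    sim <- simulate_cohort(sim_cfg)
    write_vcf(sim$table, out("cohort.vcf"))
    write_labels(sim$labels, out("labels.tsv"))
    write.table(sim$truth$samples, out("truth_samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    table <- sim$table
    labels <- sim$labels
    res$truth <- sim$truth
    tracks <- simulate_depth_tracks(sim_cfg,
                                    sample_ids = head(sim$table$samples, 4))
  } else {
    table <- read_vcf(config$vcf)
    labels <- read_labels(config$labels)
  }
  res$labels <- labels

  if ("filter" %in% stages) {
    table <- filter_chain(table, maf_min = config$maf_min,
                          dp_min = config$dp_min, gq_min = config$gq_min)
    log <- attr(table, "filter_log")
    write.table(log, out("filter_log.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    table <- thin_one_per_marker(table)
    write_vcf(table, out("filtered.vcf"))
  }
  res$table <- table

  panel <- NULL
  if ("panel" %in% stages) {
    panel <- ascertain_panel(table, labels)
    write_panel(panel, out("panel.tsv"))
    res$panel <- panel
  }

  if ("triangle" %in% stages) {
    scores <- score_cohort(table, panel)
    write.table(scores, out("triangle_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (config$plots) {
      try_plot(triangle_report(scores, out("triangle"), labels = labels),
               "triangle")
    }
    res$scores <- scores
  }

  if ("dosage" %in% stages) {
    e_samples <- names(labels)[labels == "E"]
    if (length(e_samples) == 0L) e_samples <- table$samples
    dosage <- dosage_table(table, panel, sample_ids = e_samples,
                           min_total_depth = config$min_total_depth,
                           margin = config$margin)
    write.table(dosage, out("dosage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (config$plots) {
      profiles <- lapply(e_samples, function(s) {
        ratio_profile(table, panel, s,
                      min_total_depth = config$min_total_depth)
      })
      try_plot(dosage_histogram_plot(profiles, out("dosage_histograms.pdf")),
               "dosage histograms")
    }
    res$dosage <- dosage
  }

  if ("ploidy" %in% stages) {
    fits <- list()
    skipped <- character(0)
    for (s in table$samples) {
      fit <- tryCatch(
        infer_ploidy(table, s, min_depth = config$gmm_min_depth,
                     ratio_bounds = config$ratio_bounds,
                     gq_min = config$gq_min,
                     min_sites = config$gmm_min_sites),
        error = function(e) e
      )
      if (inherits(fit, "error")) skipped <- c(skipped, s) else fits[[s]] <- fit
    }
    if (length(skipped)) {
      message("ploidy stage skipped ", length(skipped),
              " sample(s) with too few informative sites: ",
              paste(skipped, collapse = ", "))
    }
    if (length(fits)) {
      ploidy_df <- do.call(rbind, lapply(fits, function(f) {
        data.frame(sample_id = f$sample_id, n_sites = f$n_sites,
                   noise_fraction = f$noise_fraction,
                   delta_diploid = f$delta[["2"]],
                   delta_triploid = f$delta[["3"]],
                   delta_tetraploid = f$delta[["4"]],
                   best_ploidy = f$best_ploidy, r_squared = f$r_squared,
                   stringsAsFactors = FALSE)
      }))
      rownames(ploidy_df) <- NULL
      write.table(ploidy_df, out("ploidy.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      res$ploidy <- ploidy_df
    }
  }

  if ("ancestry" %in% stages) {
    q <- do.call(rbind, lapply(table$samples, function(s) {
      est <- estimate_q_supervised(table, labels, s, panel = res$panel)
      data.frame(sample_id = est$sample_id, q_l = est$q_l,
                 n_loci = est$n_loci, mode = est$mode,
                 stringsAsFactors = FALSE)
    }))
    write.table(q, out("ancestry.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$ancestry <- q
    pca <- run_pca(table)
    pca_df <- data.frame(sample_id = rownames(pca$coords), pca$coords,
                         row.names = NULL)
    write.table(pca_df, out("pca.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$pca <- pca
  }

  if ("coverage" %in% stages) {
    if (is.null(tracks)) {
      files <- list.files(config$depth_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      tracks <- lapply(files, read_depth_table)
      names(tracks) <- sub("\\.tsv$", "", basename(files))
    }
    cov <- summarize_coverage(tracks, window = config$window)
    write.table(cov$per_marker, out("coverage_per_marker.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cov$per_sample, out("coverage_per_sample.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (config$plots) try_plot(plot_coverage(cov, out("coverage.pdf")), "coverage")
    res$coverage <- cov
  }

  if ("report" %in% stages) {
    report <- data.frame(sample_id = table$samples,
                         group = unname(labels[table$samples]),
                         stringsAsFactors = FALSE)
    merge_in <- function(report, df, cols) {
      if (is.null(df)) return(report)
      merge(report, df[, c("sample_id", cols), drop = FALSE],
            by = "sample_id", all.x = TRUE, sort = FALSE)
    }
    report <- merge_in(report, res$scores, c("hybrid_index", "interclass_het"))
    report <- merge_in(report, res$dosage, c("mean_ratio", "call"))
    report <- merge_in(report, res$ploidy, c("best_ploidy", "r_squared"))
    report <- merge_in(report, res$ancestry, "q_l")
    dosage_ploidy <- c(diploid = 2L, triploid_LL_R = 3L, triploid_L_RR = 3L,
                       ambiguous = NA_integer_)
    if (!is.null(report$call) && !is.null(report$best_ploidy)) {
      report$ploidy_consistent <- dosage_ploidy[report$call] == report$best_ploidy
    }
    report <- report[match(table$samples, report$sample_id), , drop = FALSE]
    write.table(report, out("report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$report <- report
  }
  invisible(res)
}
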