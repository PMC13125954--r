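#' Allele-depth-ratio profile at diagnostic loci
#'
#' For one sample, computes at every panel locus the ratio of the sequencing
#' depth of the lessonae (L) allele to the summed depth of the two parental
#' alleles. Ratios are depth-based, taken straight from the AD field
#' regardless of the called genotype. The expectation is the L-genome dosage
#' fraction: 0.5 for a diploid hybrid, 2/3 for an LLR triploid, 1/3 for LRR.
#'
#' @param table a [variant_table()] with AD populated at panel loci.
#' @param panel a `diagnostic_panel`.
#' @param sample_id sample to profile.
#' @param min_total_depth minimum summed L+R depth for a locus to contribute
#'   (default 1).
#' @param nbins number of histogram bins on `[0, 1]` (default 20).
#' @return an `allele_ratio_profile`: list with `sample_id`, `ratios`,
#'   `mean_ratio`, `breaks`, `density` (normalized bin counts, sums to 1),
#'   `n_sites`.
#' @export
ratio_profile <- function(table, panel, sample_id, min_total_depth = 1L,
                          nbins = 20L) {
  if (!(sample_id %in% table$samples)) stop("unknown sample: ", sample_id)
  mp <- match_panel(table, panel)
  ad <- ad_depths(table)
  ref_d <- ad$ref[mp$row, sample_id]
  alt_d <- ad$alt[mp$row, sample_id]
  l_d <- ifelse(mp$l_is_alt, alt_d, ref_d)
  r_d <- ifelse(mp$l_is_alt, ref_d, alt_d)
  tot <- l_d + r_d
  use <- !is.na(tot) & tot >= max(1L, min_total_depth)
  if (!any(use)) stop("no panel locus with usable depth for sample ", sample_id)
  ratios <- l_d[use] / tot[use]
  breaks <- seq(0, 1, length.out = nbins + 1L)
  counts <- tabulate(pmin(nbins, findInterval(ratios, breaks,
                                              rightmost.closed = TRUE)),
                     nbins)
  structure(
    list(
      sample_id = sample_id,
      ratios = ratios,
      mean_ratio = mean(ratios),
      breaks = breaks,
      density = counts / sum(counts),
      n_sites = length(ratios)
    ),
    class = "allele_ratio_profile"
  )
}

#' @export
print.allele_ratio_profile <- function(x, ...) {
  cat(sprintf("<allele_ratio_profile> %s: mean L-ratio %.4f over %d sites\n",
              x$sample_id, x$mean_ratio, x$n_sites))
  invisible(x)
}

#' Classify genome dosage from an allele-ratio profile
#'
#' Nearest-centre rule on the mean L-allele depth ratio: centres at 0.5
#' (diploid LR), 2/3 (triploid LLR) and 1/3 (triploid LRR); a sample whose
#' mean ratio is further than `margin` from every centre is `ambiguous`.
#'
#' @param profile an [ratio_profile()] result.
#' @param centers named numeric vector of class centres.
#' @param margin maximum distance from the nearest centre (default 0.07).
#' @param min_sites minimum informative sites for a confident call
#'   (default 50); fewer triggers a warning.
#' @return a `dosage_call`: list with `sample_id`, `call`, `mean_ratio`,
#'   `decision_statistic`, `n_sites`.
#' @export
classify_dosage <- function(profile,
                            centers = c(diploid = 0.5,
                                        triploid_LL_R = 2 / 3,
                                        triploid_L_RR = 1 / 3),
                            margin = 0.07, min_sites = 50L) {
  if (profile$n_sites < min_sites) {
    warning("dosage call for ", profile$sample_id, " based on only ",
            profile$n_sites, " sites (< ", min_sites, ")")
  }
  d <- abs(profile$mean_ratio - centers)
  nearest <- which.min(d)
  call <- if (d[nearest] <= margin) names(centers)[nearest] else "ambiguous"
  structure(
    list(
      sample_id = profile$sample_id,
      call = call,
      mean_ratio = profile$mean_ratio,
      decision_statistic = unname(d[nearest]),
      n_sites = profile$n_sites
    ),
    class = "dosage_call"
  )
}

#' @export
print.dosage_call <- function(x, ...) {
  cat(sprintf("<dosage_call> %s: %s (mean ratio %.4f, |d| = %.4f, %d sites)\n",
              x$sample_id, x$call, x$mean_ratio, x$decision_statistic,
              x$n_sites))
  invisible(x)
}

#' Frequency-versus-allele-ratio curves for a cohort
#'
#' One normalized frequency curve per sample: diploids peak near 0.5,
#' triploids near 1/3 or 2/3.
#'
#' @param profiles list of `allele_ratio_profile`s.
#' @param out_path optional file to save the plot to.
#' @return the ggplot object, invisibly if saved.
#' @export
dosage_histogram_plot <- function(profiles, out_path = NULL) {
  if (length(profiles) == 0L) stop("no profiles to plot")
  df <- do.call(rbind, lapply(profiles, function(p) {
    mid <- (utils::head(p$breaks, -1) + p$breaks[-1]) / 2
    data.frame(sample_id = p$sample_id, ratio = mid, frequency = p$density)
  }))
  plt <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$frequency,
                                          colour = .data$sample_id)) +
    ggplot2::geom_line(show.legend = length(profiles) <= 12) +
    ggplot2::geom_vline(xintercept = c(1 / 3, 0.5, 2 / 3),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "L-allele depth ratio", y = "Frequency of SNPs") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, plt, width = 6, height = 4)
    return(invisible(plt))
  }
  plt
}

#' Dosage calls for every sample in a set
#'
#' @inheritParams ratio_profile
#' @inheritParams classify_dosage
#' @param sample_ids samples to call (default: all in the table).
#' @return data.frame: sample_id, n_sites, mean_ratio, call,
#'   decision_statistic.
#' @export
dosage_table <- function(table, panel, sample_ids = table$samples,
                         min_total_depth = 1L, margin = 0.07,
                         min_sites = 50L) {
  rows <- lapply(sample_ids, function(s) {
    prof <- ratio_profile(table, panel, s, min_total_depth = min_total_depth)
    call <- suppressWarnings(
      classify_dosage(prof, margin = margin, min_sites = min_sites)
    )
    data.frame(sample_id = s, n_sites = call$n_sites,
               mean_ratio = call$mean_ratio, call = call$call,
               decision_statistic = call$decision_statistic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
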