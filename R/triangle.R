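#' Hybrid index and interclass heterozygosity for one sample
#'
#' On the diagnostic panel, the hybrid index is the fraction of a sample's
#' alleles drawn from the ridibundus (R) pool — 0 for pure lessonae, 1 for
#' pure ridibundus, 0.5 for an F1 — and the interclass heterozygosity is the
#' fraction of panel loci carrying one allele from each pool (1 for an F1, 0
#' for a pure parental). Triploids genotyped by a diploid caller are scored
#' from their called diploid genotypes; the resulting displacement toward the
#' double-dose parent is a property of the pipeline being modelled, not a bug.
#'
#' @param table a filtered [variant_table()].
#' @param panel a `diagnostic_panel` from [ascertain_panel()].
#' @param sample_id sample to score.
#' @return a `hybrid_score`: list with `sample_id`, `hybrid_index`,
#'   `interclass_het`, `n_loci`.
#' @export
score_sample <- function(table, panel, sample_id) {
  if (!(sample_id %in% table$samples)) stop("unknown sample: ", sample_id)
  mp <- match_panel(table, panel)
  cnt <- gt_allele_counts(table)
  n_alt <- cnt$n_alt[mp$row, sample_id]
  n_called <- cnt$n_called[mp$row, sample_id]
  use <- !is.na(n_called)
  n_alt <- n_alt[use]
  n_called <- n_called[use]
  l_is_alt <- mp$l_is_alt[use]
  n <- length(n_alt)
  if (n == 0L) stop("sample ", sample_id, " has no called genotype at any panel locus")
  r_count <- ifelse(l_is_alt, n_called - n_alt, n_alt)
  l_count <- n_called - r_count
  structure(
    list(
      sample_id = sample_id,
      hybrid_index = sum(r_count) / sum(n_called),
      interclass_het = mean(r_count > 0L & l_count > 0L),
      n_loci = n
    ),
    class = "hybrid_score"
  )
}

#' @export
print.hybrid_score <- function(x, ...) {
  cat(sprintf("<hybrid_score> %s: h = %.4f, het = %.4f (%d loci)\n",
              x$sample_id, x$hybrid_index, x$interclass_het, x$n_loci))
  invisible(x)
}

#' Score every sample of a table on a diagnostic panel
#' @inheritParams score_sample
#' @param sample_ids samples to score (default: all).
#' @return data.frame: sample_id, hybrid_index, interclass_het, n_loci.
#' @export
score_cohort <- function(table, panel, sample_ids = table$samples) {
  rows <- lapply(sample_ids, function(s) {
    sc <- score_sample(table, panel, s)
    data.frame(sample_id = sc$sample_id, hybrid_index = sc$hybrid_index,
               interclass_het = sc$interclass_het, n_loci = sc$n_loci,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hardy-Weinberg boundary of the triangle plot
#'
#' Minimum interclass heterozygosity attainable at hybrid index `h` under
#' Hardy-Weinberg equilibrium: `2 h (1 - h)`. Individuals cannot fall below
#' this curve in a randomly mating admixed population.
#'
#' @param h hybrid index, in `[0, 1]` (vectorized).
#' @return `2 * h * (1 - h)`.
#' @export
hwe_boundary <- function(h) {
  if (any(is.na(h)) || any(h < 0 | h > 1)) stop("h must lie in [0, 1]")
  2 * h * (1 - h)
}

#' Triangle plot and score table
#'
#' Writes the per-sample score table as TSV and a scatter of interclass
#' heterozygosity against hybrid index with the HWE boundary curve.
#'
#' @param scores data.frame from [score_cohort()] (or list of `hybrid_score`).
#' @param out_prefix path prefix; writes `<prefix>.tsv` and `<prefix>.pdf`.
#' @param labels optional group labels used to colour points.
#' @return invisibly, the paths written.
#' @export
triangle_report <- function(scores, out_prefix, labels = NULL) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(s) {
      data.frame(sample_id = s$sample_id, hybrid_index = s$hybrid_index,
                 interclass_het = s$interclass_het, n_loci = s$n_loci)
    }))
  }
  if (is.null(scores) || nrow(scores) == 0L) stop("no scores to report")
  tsv <- paste0(out_prefix, ".tsv")
  pdf <- paste0(out_prefix, ".pdf")
  write.table(scores, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  df <- scores
  df$group <- if (!is.null(labels)) unname(as_labels(labels)[df$sample_id]) else "sample"
  curve <- data.frame(h = seq(0, 1, length.out = 201))
  curve$het <- hwe_boundary(curve$h)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hybrid_index,
                                        y = .data$interclass_het,
                                        colour = .data$group)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$h, y = .data$het),
                       inherit.aes = FALSE, linetype = "dotted") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Hybrid index (0 = lessonae, 1 = ridibundus)",
                  y = "Interclass heterozygosity") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(pdf, p, width = 6, height = 5)
  invisible(c(table = tsv, plot = pdf))
}
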