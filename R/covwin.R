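#' Minimum depth of the best-covered contiguous window
#'
#' Over all contiguous windows of `window` bases, returns the maximum of the
#' within-window minimum depth — a per-marker coverage summary that does not
#' depend on marker length. Markers shorter than the window return the
#' whole-marker minimum. Implemented as an O(n) sliding-window minimum
#' (monotone deque).
#'
#' @param depths non-negative integer vector of per-base depths along one
#'   marker.
#' @param window window length in bases (default 100).
#' @return integer: the best window's minimum depth.
#' @export
best_window_min <- function(depths, window = 100L) {
  n <- length(depths)
  if (n == 0L) stop("empty depth track")
  if (window < 1L) stop("window must be >= 1")
  if (any(depths < 0, na.rm = TRUE) || anyNA(depths)) {
    stop("depths must be non-negative and non-missing")
  }
  if (n < window) return(min(depths))
  # monotone deque of candidate minima indices for the current window
  q <- integer(n)
  head_i <- 1L
  tail_i <- 0L
  best <- -Inf
  for (i in seq_len(n)) {
    while (tail_i >= head_i && depths[q[tail_i]] >= depths[i]) {
      tail_i <- tail_i - 1L
    }
    tail_i <- tail_i + 1L
    q[tail_i] <- i
    if (q[head_i] <= i - window) head_i <- head_i + 1L
    if (i >= window) best <- max(best, depths[q[head_i]])
  }
  as.integer(best)
}

#' Read a samtools-depth-style per-base depth table
#'
#' Three tab-separated columns (no header): marker_id, position, depth.
#' Positions are 1-based; positions absent from the file are taken as depth
#' 0, and each marker's track runs to its maximum listed position.
#'
#' @param path path to the TSV.
#' @return named list: one integer depth vector per marker.
#' @export
read_depth_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("marker_id", "pos", "depth"))
  out <- lapply(split(df, df$marker_id), function(d) {
    track <- integer(max(d$pos))
    track[d$pos] <- as.integer(d$depth)
    track
  })
  out[unique(df$marker_id)]
}

#' Write per-base depth tracks in samtools-depth style
#' @param tracks named list of integer depth vectors (one per marker).
#' @param path output TSV path.
#' @export
write_depth_table <- function(tracks, path) {
  df <- do.call(rbind, lapply(names(tracks), function(m) {
    data.frame(marker_id = m, pos = seq_along(tracks[[m]]),
               depth = tracks[[m]])
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Cohort coverage summary from per-base depth tracks
#'
#' Computes the best-window minimum depth per (marker, sample), then
#' per-marker medians across samples (with markers ranked by the sum of
#' their per-sample values, descending), per-sample medians and totals, and
#' counts of markers whose cross-sample median exceeds `hi` or falls below
#' `lo`.
#'
#' @param tracks named list (one element per sample) of named lists of depth
#'   vectors (one per marker); all samples must cover the same marker set.
#' @param window window length (default 100).
#' @param hi,lo thresholds for the well/poorly covered marker counts
#'   (defaults 100 and 10).
#' @return a `coverage_summary`: list with `matrix` (markers x samples of
#'   best-window minima), `per_marker` (marker_id, median, sum, rank),
#'   `per_sample` (sample_id, median, total), `n_hi`, `n_lo`.
#' @export
summarize_coverage <- function(tracks, window = 100L, hi = 100L, lo = 10L) {
  if (length(tracks) == 0L) stop("no samples supplied")
  marker_sets <- lapply(tracks, names)
  ref <- marker_sets[[1]]
  for (s in names(tracks)) {
    extra <- setdiff(marker_sets[[s]], ref)
    miss <- setdiff(ref, marker_sets[[s]])
    if (length(extra) || length(miss)) {
      stop("sample ", s, " marker set differs from ", names(tracks)[1],
           if (length(miss)) paste0("; missing: ", paste(head(miss, 5), collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(head(extra, 5), collapse = ", ")))
    }
  }
  m <- vapply(tracks, function(sample_tracks) {
    vapply(ref, function(mk) best_window_min(sample_tracks[[mk]], window),
           integer(1))
  }, integer(length(ref)))
  m <- matrix(m, nrow = length(ref), dimnames = list(ref, names(tracks)))
  med <- apply(m, 1, median)
  sums <- rowSums(m)
  per_marker <- data.frame(
    marker_id = ref, median = med, sum = sums,
    rank = rank(-sums, ties.method = "first"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_sample <- data.frame(
    sample_id = names(tracks),
    median = apply(m, 2, median),
    total = colSums(m),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(matrix = m, per_marker = per_marker, per_sample = per_sample,
         n_hi = sum(med > hi), n_lo = sum(med < lo),
         window = window, hi = hi, lo = lo),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    "<coverage_summary> %d marker(s) x %d sample(s), window %d; %d marker(s) with median > %d, %d with median < %d\n",
    nrow(x$matrix), ncol(x$matrix), x$window, x$n_hi, x$hi, x$n_lo, x$lo
  ))
  invisible(x)
}

#' Ranked-marker coverage plot
#'
#' Markers ordered by the sum of their per-sample best-window minima; one
#' line per sample plus the cross-sample median.
#'
#' @param summary a `coverage_summary`.
#' @param out_path optional file to save the plot to.
#' @return the ggplot object.
#' @export
plot_coverage <- function(summary, out_path = NULL) {
  ord <- order(summary$per_marker$rank)
  df <- do.call(rbind, lapply(colnames(summary$matrix), function(s) {
    data.frame(rank = seq_along(ord), depth = summary$matrix[ord, s],
               sample_id = s)
  }))
  med <- data.frame(rank = seq_along(ord),
                    depth = summary$per_marker$median[ord])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$depth,
                                        group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "steelblue") +
    ggplot2::geom_line(data = med,
                       ggplot2::aes(x = .data$rank, y = .data$depth),
                       inherit.aes = FALSE, colour = "black") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "Marker rank (by summed coverage)",
                  y = "Best-window minimum depth") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = 7, height = 4)
    return(invisible(p))
  }
  p
}
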