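#' Select allele-balance values for ploidy fitting
#'
#' Returns the alt-allele balance `alt / (ref + alt)` for every biallelic SNP
#' in one sample with summed allele depth at least `min_depth`, genotype
#' quality at least `gq_min`, and balance strictly inside `ratio_bounds`
#' (heterozygous-like sites; balances near 0 or 1 are homozygous). All
#' biallelic SNPs are used, not only the diagnostic panel, matching how
#' allele-balance ploidy callers consume whole-sample data.
#'
#' @param table a [variant_table()].
#' @param sample_id sample to extract.
#' @param min_depth minimum summed ref+alt depth (default 20).
#' @param ratio_bounds open interval of retained balances (default
#'   `c(0.1, 0.9)`).
#' @param gq_min minimum genotype quality (default 20; quality analogue of
#'   the depth cutoff, exposed as a knob).
#' @param min_sites minimum usable sites (default 100); fewer is an error.
#' @return numeric vector of allele-balance values.
#' @export
select_sites <- function(table, sample_id, min_depth = 20L,
                         ratio_bounds = c(0.1, 0.9), gq_min = 20L,
                         min_sites = 100L) {
  if (!(sample_id %in% table$samples)) stop("unknown sample: ", sample_id)
  snp <- is_biallelic_snp(table$sites)
  ad <- ad_depths(table)
  ref_d <- ad$ref[, sample_id]
  alt_d <- ad$alt[, sample_id]
  tot <- ref_d + alt_d
  gq <- table$gq[, sample_id]
  bal <- alt_d / tot
  use <- snp & !is.na(tot) & tot >= min_depth &
    !is.na(bal) & bal > ratio_bounds[1] & bal < ratio_bounds[2] &
    (is.na(gq) | gq >= gq_min)
  vals <- bal[use]
  if (length(vals) < min_sites) {
    stop("sample ", sample_id, ": only ", length(vals),
         " usable allele-balance sites (minimum ", min_sites, ")")
  }
  vals
}

# --- weighted EM core -------------------------------------------------------

# Weighted EM for a K-component Gaussian mixture with common variance.
# Means are fixed when fixed_means = TRUE, otherwise free; mixture
# proportions are fixed at pi0 when fixed_weights = TRUE (the fixed ploidy
# models pin both means and equal proportions, leaving only the variance
# free, so that e.g. the tetraploid model cannot collapse onto the diploid
# one). Weights w_i are per-observation multiplicities in [0, 1] (from
# denoising). Monotone in the weighted log-likelihood; variance clamped at
# var_floor.
gmm_em <- function(x, w, means, pi0 = NULL, var0 = 0.01,
                   fixed_means = TRUE, fixed_weights = fixed_means,
                   max_iter = 500L, tol = 1e-8, var_floor = 1e-4) {
  k <- length(means)
  mu <- means
  pi_k <- pi0 %||% rep(1 / k, k)
  s2 <- max(var0, var_floor)
  wsum <- sum(w)
  loglik <- -Inf
  clamped <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) pi_k[j] * stats::dnorm(x, mu[j], sqrt(s2)),
                   numeric(length(x)))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    new_ll <- sum(w * log(tot))
    resp <- dens / tot
    nk <- colSums(w * resp)
    if (!fixed_weights) pi_k <- nk / wsum
    if (!fixed_means) {
      mu <- ifelse(nk > 0, colSums(w * resp * x) / nk, mu)
    }
    s2_new <- sum(vapply(seq_len(k),
                         function(j) sum(w * resp[, j] * (x - mu[j])^2),
                         numeric(1))) / wsum
    if (s2_new < var_floor) {
      s2_new <- var_floor
      clamped <- TRUE
    }
    s2 <- s2_new
    if (is.finite(loglik) && abs(new_ll - loglik) < tol * (abs(new_ll) + 1)) {
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  if (clamped) warning("mixture variance hit floor ", var_floor)
  # log-likelihood at the returned parameters
  dens <- matrix(vapply(seq_len(k),
                        function(j) pi_k[j] * stats::dnorm(x, mu[j], sqrt(s2)),
                        numeric(length(x))), ncol = k)
  tot <- rowSums(dens)
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  list(means = mu, weights = pi_k, var = s2, loglik = sum(w * log(tot)),
       n_iter = iter)
}

# Weighted mixture log-likelihood at given parameters (no fitting).
gmm_loglik <- function(x, w, means, pi_k, s2) {
  dens <- matrix(vapply(seq_along(means),
                        function(j) pi_k[j] * stats::dnorm(x, means[j], sqrt(s2)),
                        numeric(length(x))), ncol = length(means))
  tot <- rowSums(dens)
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  sum(w * log(tot))
}

#' Remove uniform background noise from allele-balance values
#'
#' Fits, by EM, a mixture of a uniform(0, 1) noise component and a free
#' 3-component Gaussian mixture (free means, common variance). Returns the
#' per-site posterior probability of the non-noise components — used as
#' weights by [fit_ploidy_models()] — and the estimated noise fraction.
#'
#' @param values allele-balance values in (0, 1).
#' @param min_sites minimum number of values (default 100).
#' @param max_iter,tol EM controls; `tol` is relative to the current
#'   log-likelihood magnitude.
#' @return list with `weights` (per-site, in `[0, 1]`), `noise_fraction`,
#'   `converged`.
#' @export
denoise <- function(values, min_sites = 100L, max_iter = 1000L, tol = 1e-6) {
  n <- length(values)
  if (n < min_sites) {
    stop("denoise: only ", n, " values (minimum ", min_sites, ")")
  }
  mu <- c(0.25, 0.5, 0.75)
  pi_g <- rep(0.3, 3)
  pi_u <- 0.1
  s2 <- 0.01
  loglik <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dg <- vapply(1:3, function(j) pi_g[j] * stats::dnorm(values, mu[j], sqrt(s2)),
                 numeric(n))
    dg <- matrix(dg, ncol = 3)
    du <- pi_u * stats::dunif(values)
    tot <- rowSums(dg) + du
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    new_ll <- sum(log(tot))
    rg <- dg / tot
    ru <- du / tot
    nk <- colSums(rg)
    pi_g <- nk / n
    pi_u <- sum(ru) / n
    mu <- ifelse(nk > 0, colSums(rg * values) / nk, mu)
    s2 <- sum(vapply(1:3, function(j) sum(rg[, j] * (values - mu[j])^2),
                     numeric(1))) / max(sum(nk), .Machine$double.eps)
    s2 <- max(s2, 1e-4)
    if (is.finite(loglik) && abs(new_ll - loglik) < tol * (abs(new_ll) + 1)) {
      converged <- TRUE
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  if (!converged) {
    warning("denoise EM did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  dg <- matrix(vapply(1:3, function(j) pi_g[j] * stats::dnorm(values, mu[j], sqrt(s2)),
                      numeric(n)), ncol = 3)
  du <- pi_u * stats::dunif(values)
  tot <- rowSums(dg) + du
  tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
  list(weights = rowSums(dg) / tot, noise_fraction = pi_u,
       converged = converged)
}

# Canonical fixed-mean sets per ploidy hypothesis.
ploidy_means <- list(
  `2` = 0.5,
  `3` = c(1 / 3, 2 / 3),
  `4` = c(0.25, 0.5, 0.75)
)

# Embed a fitted fixed model as a 3-component mixture with duplicated means.
# The density (hence the log-likelihood) is unchanged, so a free EM started
# here can only improve on the fixed model's fit.
embed_as_free <- function(fit) {
  k <- length(fit$means)
  if (k == 3L) {
    list(means = fit$means, weights = fit$weights, var = fit$var)
  } else if (k == 2L) {
    list(means = c(fit$means[1], fit$means[2], fit$means[2]),
         weights = c(fit$weights[1], fit$weights[2] / 2, fit$weights[2] / 2),
         var = fit$var)
  } else {
    list(means = rep(fit$means[1], 3), weights = rep(1 / 3, 3), var = fit$var)
  }
}

#' Fit free and fixed Gaussian mixtures and select the ploidy
#'
#' Fits to (optionally denoised-weighted) allele-balance values: a free
#' 3-component Gaussian mixture (free means, free weights, common variance)
#' and three fixed models — diploid (mean 1/2), triploid (1/3, 2/3) and
#' tetraploid (1/4, 1/2, 3/4) — with equal fixed mixture proportions and a
#' common free variance (only the variance is fitted, so a higher-ploidy
#' model cannot collapse onto a lower one and the models discriminate).
#' The ploidy whose fixed model loses the least log-likelihood relative to
#' the free model (`delta = loglik_free - loglik_fixed`) is selected, ties
#' resolved toward lower ploidy. The free fit is warm-started from every
#' fitted fixed model (plus canonical and quantile starts), so
#' `loglik_free >= loglik_fixed[p]` holds up to EM tolerance by construction.
#'
#' @param values allele-balance values in (0, 1).
#' @param weights optional per-site weights from [denoise()] (default 1).
#' @param nbins histogram bins on (0, 1) for the R-squared of the best fixed
#'   model against the empirical distribution (default 100).
#' @param max_iter,tol EM controls; `tol` is relative to the current
#'   log-likelihood magnitude.
#' @return a `ploidy_fit`: list with `n_sites`, `loglik_free`,
#'   `loglik_fixed` (named by ploidy), `delta`, `best_ploidy`, `r_squared`,
#'   `noise_fraction` (NA unless set by the caller), fitted parameters, and
#'   the input values/weights (for plotting).
#' @export
fit_ploidy_models <- function(values, weights = NULL, nbins = 100L,
                              max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(values)
  w <- weights %||% rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0))
  if (length(x) < 10L) stop("too few values (", length(x), ") to fit mixtures")

  fixed <- lapply(ploidy_means, function(m) {
    gmm_em(x, w, means = m, var0 = 0.01, fixed_means = TRUE,
           max_iter = max_iter, tol = tol)
  })
  loglik_fixed <- vapply(fixed, `[[`, numeric(1), "loglik")

  starts <- c(
    list(list(means = c(0.25, 0.5, 0.75), weights = rep(1 / 3, 3), var = 0.01)),
    lapply(fixed, embed_as_free),
    lapply(list(c(0.2, 0.5, 0.8), c(0.1, 0.5, 0.9), c(1 / 6, 0.5, 5 / 6),
                c(0.3, 0.5, 0.7), c(0.25, 0.6, 0.9)),
           function(p) list(means = unname(quantile(x, p)),
                            weights = rep(1 / 3, 3), var = 0.01))
  )
  free_fits <- lapply(starts, function(st) {
    gmm_em(x, w, means = st$means, pi0 = st$weights, var0 = st$var,
           fixed_means = FALSE, max_iter = max_iter, tol = tol)
  })
  free <- free_fits[[which.max(vapply(free_fits, `[[`, numeric(1), "loglik"))]]

  delta <- free$loglik - loglik_fixed
  best <- c(2L, 3L, 4L)[which.min(delta)]
  best_fit <- fixed[[as.character(best)]]

  # R^2 of the best fixed model's bin masses against the weighted empirical
  # histogram, both normalized over (0, 1).
  edges <- seq(0, 1, length.out = nbins + 1L)
  pred <- rowSums(vapply(seq_along(best_fit$means), function(j) {
    best_fit$weights[j] * (pnorm(edges[-1], best_fit$means[j], sqrt(best_fit$var)) -
                             pnorm(edges[-length(edges)], best_fit$means[j],
                                   sqrt(best_fit$var)))
  }, numeric(nbins)))
  pred <- pred / sum(pred)
  bin <- pmin(nbins, pmax(1L, findInterval(x, edges, rightmost.closed = TRUE)))
  emp <- vapply(seq_len(nbins), function(b) sum(w[bin == b]), numeric(1))
  emp <- emp / sum(emp)
  r2 <- 1 - sum((emp - pred)^2) / sum((emp - mean(emp))^2)
  r2 <- min(max(r2, 0), 1)

  structure(
    list(
      sample_id = NA_character_,
      n_sites = length(x),
      loglik_free = free$loglik,
      loglik_fixed = loglik_fixed,
      delta = delta,
      best_ploidy = best,
      r_squared = r2,
      noise_fraction = NA_real_,
      free_fit = free,
      fixed_fits = fixed,
      values = x,
      weights = w
    ),
    class = "ploidy_fit"
  )
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf(
    "<ploidy_fit> %s: best ploidy %d (delta 2/3/4 = %.2f/%.2f/%.2f, R2 = %.3f, %d sites)\n",
    x$sample_id %||% "?", x$best_ploidy, x$delta[1], x$delta[2], x$delta[3],
    x$r_squared, x$n_sites
  ))
  invisible(x)
}

#' Full per-sample ploidy inference
#'
#' Convenience wrapper: [select_sites()] then [denoise()] then
#' [fit_ploidy_models()].
#'
#' @inheritParams select_sites
#' @param nbins passed to [fit_ploidy_models()].
#' @return a `ploidy_fit` with `sample_id` and `noise_fraction` filled in.
#' @export
infer_ploidy <- function(table, sample_id, min_depth = 20L,
                         ratio_bounds = c(0.1, 0.9), gq_min = 20L,
                         min_sites = 100L, nbins = 100L) {
  vals <- select_sites(table, sample_id, min_depth = min_depth,
                       ratio_bounds = ratio_bounds, gq_min = gq_min,
                       min_sites = min_sites)
  dn <- denoise(vals, min_sites = min_sites)
  fit <- fit_ploidy_models(vals, weights = dn$weights, nbins = nbins)
  fit$sample_id <- sample_id
  fit$noise_fraction <- dn$noise_fraction
  fit
}

#' Ploidy report: summary table and annotated histograms
#'
#' @param fits list of `ploidy_fit`s.
#' @param out_prefix path prefix; writes `<prefix>.tsv` and `<prefix>.pdf`.
#' @return invisibly, the summary data.frame.
#' @export
ploidy_report <- function(fits, out_prefix) {
  if (length(fits) == 0L) stop("no ploidy fits to report")
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      sample_id = f$sample_id, n_sites = f$n_sites,
      noise_fraction = f$noise_fraction,
      delta_diploid = f$delta[["2"]], delta_triploid = f$delta[["3"]],
      delta_tetraploid = f$delta[["4"]],
      best_ploidy = f$best_ploidy, r_squared = f$r_squared,
      stringsAsFactors = FALSE
    )
  }))
  write.table(df, paste0(out_prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hist_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(sample_id = f$sample_id, value = f$values, w = f$weights)
  }))
  dens_df <- do.call(rbind, lapply(fits, function(f) {
    grid <- seq(0.01, 0.99, length.out = 199)
    bf <- f$fixed_fits[[as.character(f$best_ploidy)]]
    y <- rowSums(vapply(seq_along(bf$means), function(j) {
      bf$weights[j] * stats::dnorm(grid, bf$means[j], sqrt(bf$var))
    }, numeric(length(grid))))
    data.frame(sample_id = f$sample_id, value = grid, dens = y,
               label = sprintf("%s: %s, R2 = %.2f", f$sample_id,
                               c(`2` = "diploid", `3` = "triploid",
                                 `4` = "tetraploid")[as.character(f$best_ploidy)],
                               f$r_squared))
  }))
  p <- ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density),
                                         weight = .data$w),
                            bins = 40, fill = "grey70") +
    ggplot2::geom_line(data = dens_df,
                       ggplot2::aes(x = .data$value, y = .data$dens),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~sample_id, scales = "free_y") +
    ggplot2::labs(x = "Allele balance", y = "Density") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paste0(out_prefix, ".pdf"), p, width = 9, height = 7)
  invisible(df)
}
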