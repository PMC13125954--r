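#' Supervised two-pool ancestry proportion for one sample
#'
#' Maximum-likelihood estimate of the lessonae-pool ancestry fraction `q_l`
#' under the standard two-pool admixture binomial model: with alt-allele
#' frequencies `p_L`, `p_R` estimated from the labelled parental samples, the
#' sample's expected alt frequency at locus j is
#' `f_j = q_l * p_Lj + (1 - q_l) * p_Rj` and the genotype log-likelihood
#' `sum_j g_j log f_j + (2 - g_j) log(1 - f_j)` is maximized over
#' `q_l` in `[0, 1]`. When a diagnostic panel is supplied, parental
#' frequencies are exactly 0/1 at every locus and the maximizer has the
#' closed form `q_l = (L-allele count) / (2 n_loci)`, which is used directly.
#'
#' @param table a filtered [variant_table()].
#' @param labels group labels (L/R parentals define the pools).
#' @param sample_id sample to estimate.
#' @param panel optional `diagnostic_panel`; when given, the closed-form
#'   estimator on panel loci is used.
#' @param pseudocount added to parental allele counts as
#'   `(count + pseudocount) / (2 n + 2 pseudocount)` to keep frequencies off
#'   0 and 1 in the general mode (default 0.5).
#' @param tol optimizer tolerance (default 1e-6).
#' @return an `ancestry_estimate`: list with `sample_id`, `q_l`, `loglik`,
#'   `n_loci`, `mode = "supervised"`.
#' @export
estimate_q_supervised <- function(table, labels, sample_id, panel = NULL,
                                  pseudocount = 0.5, tol = 1e-6) {
  if (!(sample_id %in% table$samples)) stop("unknown sample: ", sample_id)
  cnt <- gt_allele_counts(table)
  if (!is.null(panel)) {
    mp <- match_panel(table, panel)
    n_alt <- cnt$n_alt[mp$row, sample_id]
    n_called <- cnt$n_called[mp$row, sample_id]
    use <- !is.na(n_called) & n_called > 0
    if (!any(use)) stop("no informative panel locus for sample ", sample_id)
    l_count <- ifelse(mp$l_is_alt[use], n_alt[use], n_called[use] - n_alt[use])
    q <- sum(l_count) / sum(n_called[use])
    g <- l_count
    m <- n_called[use]
    ll <- sum(g * log(pmax(q, .Machine$double.xmin)) +
                (m - g) * log(pmax(1 - q, .Machine$double.xmin)))
    return(structure(
      list(sample_id = sample_id, q_l = q, loglik = ll,
           n_loci = sum(use), mode = "supervised"),
      class = "ancestry_estimate"
    ))
  }
  labels <- labels_for_table(table, labels)
  pool_freq <- function(group) {
    samples <- table$samples[labels == group]
    if (length(samples) == 0L) stop("no samples labelled ", group)
    alt <- rowSums(cnt$n_alt[, samples, drop = FALSE], na.rm = TRUE)
    tot <- rowSums(cnt$n_called[, samples, drop = FALSE], na.rm = TRUE)
    (alt + pseudocount) / (tot + 2 * pseudocount)
  }
  p_l <- pool_freq("L")
  p_r <- pool_freq("R")
  g <- cnt$n_alt[, sample_id]
  m <- cnt$n_called[, sample_id]
  use <- !is.na(m) & m > 0
  if (!any(use)) stop("no informative locus for sample ", sample_id)
  g <- g[use]
  m <- m[use]
  p_l <- p_l[use]
  p_r <- p_r[use]
  nll <- function(q) {
    f <- q * p_l + (1 - q) * p_r
    f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
    -sum(g * log(f) + (m - g) * log(1 - f))
  }
  opt <- optimize(nll, c(0, 1), tol = tol)
  structure(
    list(sample_id = sample_id, q_l = opt$minimum, loglik = -opt$objective,
         n_loci = sum(use), mode = "supervised"),
    class = "ancestry_estimate"
  )
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf("<ancestry_estimate> %s: q_l = %.4f (%s, %d loci)\n",
              x$sample_id, x$q_l, x$mode, x$n_loci))
  invisible(x)
}

#' Unsupervised two-pool admixture estimation (K = 2)
#'
#' Joint EM over pool allele frequencies and per-sample ancestry fractions
#' under the binomial admixture model, run `n_replicates` times from seeded
#' random starts; the replicate with the best log-likelihood is returned.
#' When parental labels are available the pools are aligned so that pool 1
#' is the lessonae pool.
#'
#' @param table a filtered [variant_table()] with at least 3 samples.
#' @param k number of ancestral pools; only 2 is supported.
#' @param n_replicates random restarts (default 25).
#' @param max_iter,tol EM controls.
#' @param seed RNG seed for the restarts.
#' @param labels optional group labels used only to orient the two pools.
#' @return data.frame: sample_id, q_l, loglik, n_loci, mode
#'   (`"unsupervised"`), with the pool allele frequencies in the
#'   `"pool_freqs"` attribute.
#' @export
estimate_q_unsupervised <- function(table, k = 2L, n_replicates = 25L,
                                    max_iter = 500L, tol = 1e-6, seed = 1L,
                                    labels = NULL) {
  if (k != 2L) stop("only K = 2 is supported (two parental gene pools)")
  ns <- length(table$samples)
  if (ns < 3L) stop("unsupervised estimation needs >= 3 samples, got ", ns)
  cnt <- gt_allele_counts(table)
  g <- t(cnt$n_alt)     # samples x loci
  m <- t(cnt$n_called)
  use_loci <- colSums(is.na(m)) == 0L & apply(g, 2, function(col) length(unique(col)) > 1L)
  if (!any(use_loci)) stop("no informative loci for admixture estimation")
  g <- g[, use_loci, drop = FALSE]
  m <- m[, use_loci, drop = FALSE]
  nl <- ncol(g)

  run_once <- function(rep_seed) {
    with_seed(rep_seed, {
      q <- runif(ns, 0.05, 0.95)
      f <- matrix(runif(2L * nl, 0.05, 0.95), nrow = 2L)
      loglik <- -Inf
      for (iter in seq_len(max_iter)) {
        fbar <- q %o% f[1, ] + (1 - q) %o% f[2, ]        # samples x loci
        fbar <- pmin(pmax(fbar, 1e-9), 1 - 1e-9)
        new_ll <- sum(g * log(fbar) + (m - g) * log(1 - fbar))
        # expected allele-copy contributions per pool
        a1 <- g * (q %o% f[1, ]) / fbar
        a2 <- g - a1
        b1 <- (m - g) * (q %o% (1 - f[1, ])) / (1 - fbar)
        b2 <- (m - g) - b1
        q <- rowSums(a1 + b1) / rowSums(m)
        q <- pmin(pmax(q, 1e-9), 1 - 1e-9)
        f1 <- colSums(a1) / pmax(colSums(a1 + b1), 1e-12)
        f2 <- colSums(a2) / pmax(colSums(a2 + b2), 1e-12)
        f <- rbind(pmin(pmax(f1, 1e-6), 1 - 1e-6),
                   pmin(pmax(f2, 1e-6), 1 - 1e-6))
        if (is.finite(loglik) && abs(new_ll - loglik) < tol) {
          loglik <- new_ll
          break
        }
        loglik <- new_ll
      }
      if (iter == max_iter) {
        warning("admixture EM replicate did not converge in ", max_iter,
                " iterations; using best iterate")
      }
      list(q = q, f = f, loglik = loglik)
    })
  }
  rep_seed <- function(r) {
    # keep derived seeds inside 32-bit integer range
    as.integer((as.numeric(seed) * 1009 + r * 7919) %% 2147483647)
  }
  reps <- lapply(seq_len(n_replicates), function(r) run_once(rep_seed(r)))
  best <- reps[[which.max(vapply(reps, `[[`, numeric(1), "loglik"))]]

  q <- best$q
  f <- best$f
  if (!is.null(labels)) {
    lab <- as_labels(labels)[table$samples]
    if (any(lab == "L", na.rm = TRUE)) {
      if (mean(q[which(lab == "L")]) < 0.5) {
        q <- 1 - q
        f <- f[2:1, , drop = FALSE]
      }
    }
  }
  out <- data.frame(
    sample_id = table$samples, q_l = q, loglik = best$loglik,
    n_loci = nl, mode = "unsupervised", stringsAsFactors = FALSE
  )
  attr(out, "pool_freqs") <- f
  out
}

#' Principal component analysis of genotype dosages
#'
#' Standard population-genetic PCA: the samples-by-loci alt-allele dosage
#' matrix is column-centered and scaled by the binomial standard deviation
#' `sqrt(p (1 - p))` of each locus, then decomposed by SVD.
#'
#' @param table a filtered [variant_table()] with >= 2 samples and >= 2 loci
#'   (monomorphic loci are dropped).
#' @param n_components number of components to return (default 2).
#' @return a `pca_result`: list with `coords` (samples x components, columns
#'   `PC1`, `PC2`, ...) and `var_frac` (fraction of total variance per
#'   component, non-increasing).
#' @export
run_pca <- function(table, n_components = 2L) {
  if (length(table$samples) < 2L) stop("PCA needs >= 2 samples")
  cnt <- gt_allele_counts(table)
  g <- t(cnt$n_alt)
  if (any(is.na(g))) stop("PCA requires complete genotypes (filter first)")
  p <- colMeans(g) / 2
  v <- colMeans(g^2) - colMeans(g)^2
  keep <- p > 0 & p < 1 & v > 0
  if (!any(keep)) stop("all loci are monomorphic or constant; PCA undefined")
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  s <- svd(x)
  k <- min(n_components, length(s$d))
  coords <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  rownames(coords) <- table$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(coords = coords, var_frac = (s$d^2 / sum(s$d^2))[seq_len(k)]),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d sample(s), %d component(s); variance: %s\n",
              nrow(x$coords), ncol(x$coords),
              paste(sprintf("%.1f%%", 100 * x$var_frac), collapse = ", ")))
  invisible(x)
}
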