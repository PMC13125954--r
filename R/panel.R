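#' Ascertain species-diagnostic SNPs between the two parental pools
#'
#' A locus enters the panel when every called allele in every L-labelled
#' sample is one state and every called allele in every R-labelled sample is
#' the other state (100% diagnostic fixed difference). Hybrid (`E`) and
#' unknown (`U`) samples play no part in ascertainment. Loci with a missing
#' parental genotype, or with any heterozygous parental, are excluded.
#'
#' @param table a filtered [variant_table()] (biallelic SNPs, no missing
#'   genotypes).
#' @param labels group labels (named vector or two-column data.frame; see
#'   [read_labels()]). At least one `L` and one `R` sample are required.
#' @return a `diagnostic_panel`: data.frame with columns `marker_id`, `pos`,
#'   `l_allele`, `r_allele`, plus attributes `n_l_samples`, `n_r_samples`.
#' @export
ascertain_panel <- function(table, labels) {
  labels <- labels_for_table(table, labels)
  l_samples <- table$samples[labels == "L"]
  r_samples <- table$samples[labels == "R"]
  if (length(l_samples) == 0L) stop("panel ascertainment requires >= 1 sample labelled L")
  if (length(r_samples) == 0L) stop("panel ascertainment requires >= 1 sample labelled R")

  cnt <- gt_allele_counts(table)
  # Fixed state within a group: 1 (all alt), 0 (all ref), NA otherwise
  # (polymorphic, heterozygous, or missing call in the group).
  group_state <- function(samples) {
    n_alt <- cnt$n_alt[, samples, drop = FALSE]
    n_called <- cnt$n_called[, samples, drop = FALSE]
    any_na <- rowSums(is.na(n_called)) > 0L
    tot_alt <- rowSums(n_alt)
    tot <- rowSums(n_called)
    state <- rep(NA_integer_, n_sites(table))
    state[!any_na & tot_alt == 0L] <- 0L
    state[!any_na & tot_alt == tot & tot > 0L] <- 1L
    state
  }
  sl <- group_state(l_samples)
  sr <- group_state(r_samples)
  diag <- is_biallelic_snp(table$sites) & !is.na(sl) & !is.na(sr) & sl != sr
  st <- table$sites[diag, , drop = FALSE]
  sl <- sl[diag]
  panel <- data.frame(
    marker_id = st$marker_id,
    pos = st$pos,
    l_allele = ifelse(sl == 1L, st$alt, st$ref),
    r_allele = ifelse(sl == 1L, st$ref, st$alt),
    stringsAsFactors = FALSE
  )
  if (nrow(panel) == 0L) warning("no 100% diagnostic loci found; panel is empty")
  structure(panel,
            n_l_samples = length(l_samples),
            n_r_samples = length(r_samples),
            class = c("diagnostic_panel", "data.frame"))
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_panel> %d locus/loci (ascertained from %s L and %s R samples)\n",
    nrow(x), attr(x, "n_l_samples") %||% "?", attr(x, "n_r_samples") %||% "?"
  ))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Write a diagnostic panel to TSV
#' @param panel a `diagnostic_panel`.
#' @param path output path (columns marker_id, pos, l_allele, r_allele).
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a diagnostic panel from TSV
#' @param path path written by [write_panel()].
#' @return a `diagnostic_panel`.
#' @export
read_panel <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  structure(df, class = c("diagnostic_panel", "data.frame"))
}

# Panel rows matched to table records; drops panel loci absent from the table.
# Returns data.frame with table row index and whether the L allele is alt.
match_panel <- function(table, panel) {
  key_t <- paste(table$sites$marker_id, table$sites$pos)
  key_p <- paste(panel$marker_id, panel$pos)
  idx <- match(key_p, key_t)
  ok <- !is.na(idx)
  idx <- idx[ok]
  l_is_alt <- panel$l_allele[ok] == table$sites$alt[idx]
  l_is_ref <- panel$l_allele[ok] == table$sites$ref[idx]
  keep <- l_is_alt | l_is_ref
  data.frame(row = idx[keep], l_is_alt = l_is_alt[keep])
}
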