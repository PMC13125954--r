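#' In-memory multi-sample variant table
#'
#' A `variant_table` holds one row per variant site and one column per sample
#' for each of the four consumed VCF FORMAT fields. Genotypes are kept as VCF
#' strings (`"0/1"`, `"./."`, triploid `"0/0/1"`, ...) and allele depths as
#' comma-joined strings exactly as they appear in the AD field, so that a
#' write/read round trip preserves every consumed field.
#'
#' @param sites data.frame with columns `marker_id`, `pos`, `ref`, `alt`
#'   (alt may be a comma-separated list for multi-allelic records, which are
#'   retained on read so the filter chain can reject them).
#' @param gt,ad character matrices (sites x samples): genotype strings and
#'   comma-joined per-allele depths (`"."` when absent).
#' @param dp,gq integer matrices (sites x samples); `NA` when absent.
#' @param samples character vector of sample ids, in column order.
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, ad, dp, gq, samples) {
  stopifnot(
    is.data.frame(sites),
    all(c("marker_id", "pos", "ref", "alt") %in% names(sites)),
    nrow(sites) == nrow(gt) || nrow(sites) == 0L
  )
  n <- nrow(sites)
  s <- length(samples)
  shape <- function(m, mode) {
    m <- matrix(m, nrow = n, ncol = s, dimnames = list(NULL, samples))
    storage.mode(m) <- mode
    m
  }
  obj <- structure(
    list(
      sites = data.frame(
        marker_id = as.character(sites$marker_id),
        pos = as.integer(sites$pos),
        ref = as.character(sites$ref),
        alt = as.character(sites$alt),
        stringsAsFactors = FALSE
      ),
      gt = shape(gt, "character"),
      ad = shape(ad, "character"),
      dp = shape(dp, "integer"),
      gq = shape(gq, "integer"),
      samples = as.character(samples)
    ),
    class = "variant_table"
  )
  validate_variant_table(obj)
}

validate_variant_table <- function(x) {
  n <- nrow(x$sites)
  for (f in c("gt", "ad", "dp", "gq")) {
    if (nrow(x[[f]]) != n || ncol(x[[f]]) != length(x$samples)) {
      stop("variant_table: field '", f, "' has wrong dimensions")
    }
  }
  if (any(x$sites$pos < 1L, na.rm = TRUE)) stop("variant_table: positions must be 1-based (>= 1)")
  x
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "<variant_table> %d site(s) x %d sample(s)\n",
    nrow(x$sites), length(x$samples)
  ))
  if (nrow(x$sites) > 0) {
    cat("  markers:", length(unique(x$sites$marker_id)), "\n")
  }
  invisible(x)
}

#' Number of variant sites in a table
#' @param table a `variant_table`
#' @return integer count of records
#' @export
n_sites <- function(table) nrow(table$sites)

# Row-subset every parallel component of a variant_table.
subset_sites <- function(table, idx) {
  variant_table(
    table$sites[idx, , drop = FALSE],
    table$gt[idx, , drop = FALSE],
    table$ad[idx, , drop = FALSE],
    table$dp[idx, , drop = FALSE],
    table$gq[idx, , drop = FALSE],
    table$samples
  )
}

# --- parsed views -----------------------------------------------------------

# TRUE where the genotype string contains a missing allele.
gt_missing <- function(table) {
  m <- grepl(".", table$gt, fixed = TRUE)
  dim(m) <- dim(table$gt)
  dimnames(m) <- dimnames(table$gt)
  m
}

# Counts of called alleles and of alt ('1') alleles per cell; NA when missing.
# Only meaningful for biallelic records (allele index > 1 never counted as alt).
gt_allele_counts <- function(table) {
  v <- as.vector(table$gt)
  stripped <- gsub("[|/]", "", v)
  n_called <- nchar(stripped)
  n_alt <- nchar(gsub("[^1]", "", stripped))
  miss <- grepl(".", v, fixed = TRUE)
  n_called[miss] <- NA_integer_
  n_alt[miss] <- NA_integer_
  shape <- function(x) {
    dim(x) <- dim(table$gt)
    dimnames(x) <- dimnames(table$gt)
    x
  }
  list(n_called = shape(n_called), n_alt = shape(n_alt))
}

# Ref/alt allele depths as integer matrices (first two AD entries).
ad_depths <- function(table) {
  v <- as.vector(table$ad)
  parts <- strsplit(v, ",", fixed = TRUE)
  first <- vapply(parts, function(p) p[1], character(1))
  second <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", character(1))
  to_int <- function(x) {
    x[x == "." | x == ""] <- NA_character_
    suppressWarnings(as.integer(x))
  }
  shape <- function(x) {
    dim(x) <- dim(table$ad)
    dimnames(x) <- dimnames(table$ad)
    x
  }
  list(ref = shape(to_int(first)), alt = shape(to_int(second)))
}

# Biallelic-SNP flag per record: single-base ref and single-base alt, both
# canonical nucleotides (rejects indels, spanning deletions and multi-allelics).
is_biallelic_snp <- function(sites) {
  bases <- c("A", "C", "G", "T")
  toupper(sites$ref) %in% bases & toupper(sites$alt) %in% bases
}

# --- group labels -----------------------------------------------------------

#' Read a sample-to-group label table
#'
#' Two-column tab-separated file `sample_id<TAB>group` with groups among
#' `L` (lessonae pool), `R` (ridibundus pool), `E` (esculentus hybrids) and
#' `U` (unknown).
#'
#' @param path path to the TSV (no header).
#' @return named character vector: `labels[sample_id] == group`.
#' @export
read_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("sample_id", "group"))
  as_labels(df)
}

#' Write a sample-to-group label table
#' @param labels named character vector or two-column data.frame.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  labels <- as_labels(labels)
  write.table(
    data.frame(sample_id = names(labels), group = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Normalize labels to a named character vector and validate group codes.
as_labels <- function(labels) {
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("labels must be named by sample_id")
  }
  bad <- setdiff(unique(labels), c("L", "R", "E", "U"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  labels
}

# Labels restricted to the table's samples, erroring on uncovered samples.
labels_for_table <- function(table, labels) {
  labels <- as_labels(labels)
  missing <- setdiff(table$samples, names(labels))
  if (length(missing)) {
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  }
  labels[table$samples]
}
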