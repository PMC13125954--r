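#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF v4.x file (plain or gzipped) through vcfR and extracts the
#' GT, AD, DP and GQ FORMAT fields. Record order is preserved; missing
#' genotypes stay explicit (`"./."`); multi-allelic records are retained so
#' that [filter_chain()] can reject them.
#'
#' @param path path to a `.vcf` / `.vcf.gz` file with GT, AD, DP and GQ
#'   FORMAT fields. AD is required because every downstream dosage and ploidy
#'   analysis consumes per-allele depths.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- v@fix
  gtm <- v@gt
  if (is.null(gtm) || ncol(gtm) < 2L) stop("VCF '", path, "' has no sample columns")
  fmt_keys <- unique(unlist(strsplit(gtm[, "FORMAT"], ":", fixed = TRUE)))
  for (key in c("GT", "AD", "DP", "GQ")) {
    if (!(key %in% fmt_keys) && nrow(gtm) > 0L) {
      stop("VCF '", path, "' lacks required FORMAT field ", key,
           " (GT:AD:DP:GQ are all consumed downstream)")
    }
  }
  samples <- colnames(gtm)[-1]
  n <- nrow(fix)
  ext <- function(key) {
    if (n == 0L) return(matrix(character(0), 0, length(samples),
                               dimnames = list(NULL, samples)))
    m <- vcfR::extract.gt(v, element = key, convertNA = FALSE)
    m[is.na(m)] <- "."
    m
  }
  gt <- ext("GT")
  ad <- ext("AD")
  dp_chr <- ext("DP")
  gq_chr <- ext("GQ")
  to_int <- function(m) {
    v2 <- as.vector(m)
    v2[v2 == "."] <- NA_character_
    out <- suppressWarnings(as.integer(v2))
    dim(out) <- dim(m)
    dimnames(out) <- dimnames(m)
    out
  }
  sites <- data.frame(
    marker_id = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  variant_table(sites, gt, ad, to_int(dp_chr), to_int(gq_chr), samples)
}

#' Write a variant table as a plain-text VCF v4.2 file
#'
#' Serializes the table with FORMAT `GT:AD:DP:GQ`. Output is deterministic
#' (no timestamps) so identical tables give byte-identical files, and
#' `read_vcf(write_vcf(t))` reproduces every consumed field.
#'
#' @param table a [variant_table()].
#' @param path output path (`.vcf`).
#' @export
write_vcf <- function(table, path) {
  st <- table$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridotype",
    sprintf("##contig=<ID=%s>", unique(st$marker_id)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  body <- character(0)
  if (nrow(st) > 0L) {
    fmt_na <- function(m) {
      m2 <- m
      m2[is.na(m2)] <- "."
      m2
    }
    cells <- matrix(
      paste(table$gt, table$ad, fmt_na(table$dp), fmt_na(table$gq), sep = ":"),
      nrow = nrow(st)
    )
    sample_part <- apply(cells, 1L, paste, collapse = "\t")
    body <- paste(st$marker_id, st$pos, ".", st$ref, st$alt, ".", ".", ".",
                  "GT:AD:DP:GQ", sample_part, sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Apply the variant filter chain
#'
#' Keeps biallelic SNPs with no missing genotype in any sample, per-sample
#' depth `>= dp_min` and genotype quality `>= gq_min` in every sample, and a
#' minor allele frequency (computed over the called alleles of all samples)
#' `>= maf_min`. Pass/fail reasons for every record are attached as the
#' `"filter_log"` attribute. The chain is idempotent.
#'
#' @param table a [variant_table()].
#' @param maf_min minimum minor allele frequency (default 0.1); 0 disables
#'   the MAF rule.
#' @param dp_min minimum per-sample depth (default 10).
#' @param gq_min minimum per-sample genotype quality (default 20).
#' @return the filtered [variant_table()] with a `filter_log` attribute
#'   (data.frame: marker_id, pos, pass, reason).
#' @export
filter_chain <- function(table, maf_min = 0.1, dp_min = 10L, gq_min = 20L) {
  n <- n_sites(table)
  if (n == 0L) {
    out <- table
    attr(out, "filter_log") <- data.frame(
      marker_id = character(0), pos = integer(0),
      pass = logical(0), reason = character(0)
    )
    return(out)
  }
  snp_ok <- is_biallelic_snp(table$sites)
  miss <- gt_missing(table)
  any_missing <- rowSums(miss) > 0L
  dp_fail <- rowSums(is.na(table$dp) | table$dp < dp_min) > 0L
  gq_fail <- rowSums(is.na(table$gq) | table$gq < gq_min) > 0L
  cnt <- gt_allele_counts(table)
  alt_tot <- rowSums(cnt$n_alt, na.rm = TRUE)
  all_tot <- rowSums(cnt$n_called, na.rm = TRUE)
  af <- ifelse(all_tot > 0, alt_tot / all_tot, NA_real_)
  maf <- pmin(af, 1 - af)
  maf_fail <- if (maf_min > 0) (is.na(maf) | maf < maf_min) else rep(FALSE, n)

  reasons <- character(n)
  add_reason <- function(reasons, flag, label) {
    ifelse(flag, ifelse(reasons == "", label, paste(reasons, label, sep = ",")),
           reasons)
  }
  reasons <- add_reason(reasons, !snp_ok, "not_biallelic_snp")
  reasons <- add_reason(reasons, any_missing, "missing_genotype")
  reasons <- add_reason(reasons, dp_fail, paste0("dp_lt_", dp_min))
  reasons <- add_reason(reasons, gq_fail, paste0("gq_lt_", gq_min))
  reasons <- add_reason(reasons, maf_fail, paste0("maf_lt_", maf_min))
  pass <- reasons == ""

  out <- subset_sites(table, which(pass))
  attr(out, "filter_log") <- data.frame(
    marker_id = table$sites$marker_id,
    pos = table$sites$pos,
    pass = pass,
    reason = ifelse(pass, "pass", reasons),
    stringsAsFactors = FALSE
  )
  out
}

#' Keep one SNP per marker
#'
#' Retains, for each marker (reference target sequence), the record with the
#' smallest position — a deterministic stand-in for distance-based thinning,
#' adequate because every target sequence is a single short marker.
#'
#' @param table a (typically filtered) [variant_table()].
#' @return a [variant_table()] with exactly one record per `marker_id`.
#' @export
thin_one_per_marker <- function(table) {
  st <- table$sites
  if (nrow(st) == 0L) return(table)
  ord <- order(match(st$marker_id, unique(st$marker_id)), st$pos)
  keep <- sort(ord[!duplicated(st$marker_id[ord])])
  subset_sites(table, keep)
}
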