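#' Construct a SNP table
#'
#' A `snp_table` holds a multi-sample SNP (or InDel) callset in a column-major
#' layout suited to vectorised filtering: one row per variant record plus a
#' genotype matrix and a per-sample depth matrix.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (1-based
#'   integer), `ref`, `alt` (comma-separated alternate alleles) and the INFO
#'   metrics `qd`, `fs`, `mq`, `sor`, `mqranksum` (numeric, `NA` where the
#'   caller did not emit the annotation).
#' @param gt character matrix (sites x samples) of unphased diploid genotypes
#'   `"a/b"` with allele indices `a <= b`; `NA` encodes a missing call, which
#'   is distinct from homozygous reference `"0/0"`.
#' @param dp integer matrix (sites x samples) of per-sample read depths;
#'   absent DP values are stored as 0.
#' @param samples character vector of strain identifiers, in column order.
#'
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(sites, gt, dp, samples) {
  stopifnot(is.data.frame(sites))
  needed <- c("chrom", "pos", "ref", "alt", "qd", "fs", "mq", "sor", "mqranksum")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0L) {
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  gt <- as.matrix(gt)
  dp <- as.matrix(dp)
  storage.mode(dp) <- "integer"
  sites$pos <- as.integer(sites$pos)
  obj <- structure(
    list(sites = sites, gt = gt, dp = dp, samples = as.character(samples)),
    class = "snp_table"
  )
  validate_snp_table(obj)
}

validate_snp_table <- function(x) {
  n <- nrow(x$sites)
  k <- length(x$samples)
  if (!identical(dim(x$gt), c(n, k)) || !identical(dim(x$dp), c(n, k))) {
    stop("genotype/depth matrix dimensions do not match sites x samples")
  }
  # positions strictly increasing within each chromosome
  for (chr in unique(x$sites$chrom)) {
    p <- x$sites$pos[x$sites$chrom == chr]
    if (any(diff(p) <= 0L)) {
      stop("positions not strictly increasing on ", chr)
    }
  }
  if (any(x$dp < 0L, na.rm = TRUE)) stop("negative depth")
  # allele indices must address REF or a declared ALT
  n_alleles <- 1L + n_alts(x)
  idx <- gt_allele_indices(x$gt)
  bad <- pmax(idx$a1, idx$a2) >= n_alleles & !is.na(idx$a1)
  if (any(bad, na.rm = TRUE)) {
    stop("genotype allele index exceeds declared alleles at row ",
         which(rowSums(bad, na.rm = TRUE) > 0)[1L])
  }
  x
}

n_alts <- function(x) {
  alt <- x$sites$alt
  ifelse(alt == "" | is.na(alt), 0L,
         lengths(strsplit(alt, ",", fixed = TRUE)))
}

# split "a/b" genotype strings into two integer matrices (NA for missing)
gt_allele_indices <- function(gt) {
  a1 <- suppressWarnings(as.integer(sub("/.*$", "", gt)))
  a2 <- suppressWarnings(as.integer(sub("^.*/", "", gt)))
  dim(a1) <- dim(gt)
  dim(a2) <- dim(gt)
  list(a1 = a1, a2 = a2)
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d sites x %d samples (%d chromosome%s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom)),
              if (length(unique(x$sites$chrom)) == 1L) "" else "s"))
  if (nrow(x$sites) > 0L) {
    cat("  span:",
        paste0(x$sites$chrom[1L], ":", x$sites$pos[1L]), "-",
        paste0(x$sites$chrom[nrow(x$sites)], ":", x$sites$pos[nrow(x$sites)]),
        "\n")
  }
  cat("  samples:", paste(utils::head(x$samples, 5L), collapse = ", "),
      if (length(x$samples) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Number of variant records
#' @param x a `snp_table`
#' @return integer record count
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a SNP table by row
#' @param x a `snp_table`
#' @param keep logical or integer row index
#' @return the subset `snp_table`, order preserved
#' @export
subset_sites <- function(x, keep) {
  snp_table(x$sites[keep, , drop = FALSE],
            x$gt[keep, , drop = FALSE],
            x$dp[keep, , drop = FALSE],
            x$samples)
}

#' Read a multi-sample VCF into a `snp_table`
#'
#' Parses a VCF (v4.2) with per-sample GT and DP FORMAT fields. Multi-allelic
#' records are kept as-is (no splitting); genotype comparisons downstream
#' operate on allele indices per record. Phased separators are normalised to
#' unphased and allele pairs sorted, since phase is unknowable for dikaryotic
#' heterozygotes called from short reads.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param required_info INFO keys to extract; absent keys are stored as `NA`,
#'   never as zero. Defaults to the hard-filter annotations.
#' @return a `snp_table`
#' @export
read_vcf <- function(path,
                     required_info = c("QD", "FS", "MQ", "SOR", "MQRankSum")) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) {
    stop("VCF has no sample columns: ", path)
  }
  fmt <- gt_raw[, 1L]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1L)))) {
    stop("contract error: FORMAT field 'GT' absent from one or more records")
  }
  samples <- colnames(gt_raw)[-1L]

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- normalize_gt(gt)
  dp_chr <- suppressWarnings(vcfR::extract.gt(v, element = "DP"))
  dp <- suppressWarnings(matrix(as.integer(dp_chr), nrow = nrow(gt_raw)))
  dp[is.na(dp)] <- 0L

  info_lower <- c(QD = "qd", FS = "fs", MQ = "mq", SOR = "sor",
                  MQRankSum = "mqranksum")
  info_cols <- lapply(required_info, function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  })
  names(info_cols) <- info_lower[required_info]

  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  for (key in c("qd", "fs", "mq", "sor", "mqranksum")) {
    sites[[key]] <- if (key %in% names(info_cols)) info_cols[[key]] else NA_real_
  }
  rownames(sites) <- NULL
  dimnames(gt) <- NULL
  dimnames(dp) <- NULL
  snp_table(sites, gt, dp, samples)
}

# canonical "a/b" with a<=b; "./." and partial-missing -> NA
normalize_gt <- function(gt) {
  out <- gsub("|", "/", gt, fixed = TRUE)
  out <- sub(":.*$", "", out)
  parts_a <- suppressWarnings(as.integer(sub("/.*$", "", out)))
  parts_b <- suppressWarnings(as.integer(sub("^.*/", "", out)))
  lo <- pmin(parts_a, parts_b)
  hi <- pmax(parts_a, parts_b)
  res <- ifelse(is.na(lo) | is.na(hi), NA_character_, paste0(lo, "/", hi))
  dim(res) <- dim(gt)
  res
}

#' Write a `snp_table` as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with the INFO annotations and per-sample GT:DP
#' this package consumes, so that `read_vcf(write_vcf(x))` reproduces `x`.
#'
#' @param x a `snp_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mnpkit",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Variant quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Symmetric odds ratio">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  ), con)
  if (n_sites(x) > 0L) {
    info <- apply(x$sites[, c("qd", "fs", "mq", "sor", "mqranksum")], 1L,
                  function(row) {
                    keys <- c("QD", "FS", "MQ", "SOR", "MQRankSum")
                    keep <- !is.na(row)
                    if (!any(keep)) return(".")
                    paste0(keys[keep], "=", format(row[keep], trim = TRUE,
                                                   scientific = FALSE),
                           collapse = ";")
                  })
    gt <- x$gt
    gt[is.na(gt)] <- "./."
    sample_cols <- matrix(paste0(gt, ":", x$dp), nrow = n_sites(x))
    body <- cbind(x$sites$chrom, x$sites$pos, ".", x$sites$ref,
                  ifelse(x$sites$alt == "", ".", x$sites$alt),
                  ".", "PASS", info, "GT:DP", sample_cols)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
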