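#' Quality-control thresholds for variant filtering
#'
#' Bundles the hard-filter cutoffs for SNPs and InDels, the population
#' allele-frequency and missingness limits, the summed site-depth window, and
#' the polymorphic-site screen parameters. All comparisons downstream are
#' strict exactly as stated (boundary values are retained by the hard filters,
#' removed by the strict depth window); see each filter for details.
#'
#' @param snp_qd_min,snp_fs_max,snp_mq_min,snp_sor_max,snp_mqranksum_min
#'   SNP hard-filter cutoffs (variant quality by depth, Fisher strand bias,
#'   RMS mapping quality, strand odds ratio, mapping-quality rank sum).
#' @param indel_qd_min,indel_fs_max,indel_sor_max InDel hard-filter cutoffs.
#' @param maf_min minimum minor allele frequency (computed over non-missing
#'   calls).
#' @param missing_max maximum fraction of samples with a missing genotype.
#' @param site_depth_low,site_depth_high exclusive bounds on summed per-sample
#'   depth.
#' @param per_sample_depth_min exclusive per-sample depth floor for the
#'   polymorphic screen.
#' @param identical_genotype_max_frac maximum fraction of samples allowed to
#'   share the modal genotype at a polymorphic site.
#' @return an object of class `qc_thresholds`
#' @export
qc_thresholds <- function(snp_qd_min = 2.0, snp_fs_max = 60.0,
                          snp_mq_min = 40.0, snp_sor_max = 3.0,
                          snp_mqranksum_min = -12.5,
                          indel_qd_min = 2.0, indel_fs_max = 200.0,
                          indel_sor_max = 10.0,
                          maf_min = 0.05, missing_max = 0.20,
                          site_depth_low = 10L, site_depth_high = 2000L,
                          per_sample_depth_min = 10L,
                          identical_genotype_max_frac = 0.95) {
  t <- as.list(environment())
  stopifnot(maf_min > 0, maf_min < 0.5, missing_max > 0, missing_max < 1,
            site_depth_low < site_depth_high,
            all(is.finite(unlist(t))))
  structure(t, class = "qc_thresholds")
}

#' Apply hard filters to a callset
#'
#' A record is removed iff any of the stated inequalities for its kind holds:
#' SNPs with QD < 2.0, FS > 60.0, MQ < 40.0, SOR > 3.0 or MQRankSum < -12.5;
#' InDels with QD < 2.0, FS > 200.0 or SOR > 10.0 (defaults). An absent
#' annotation never triggers removal. Record order is preserved.
#'
#' @param x a `snp_table`
#' @param kind `"snp"` or `"indel"`
#' @param thresholds a [qc_thresholds()]
#' @return the filtered `snp_table`
#' @export
apply_hard_filters <- function(x, kind = c("snp", "indel"),
                               thresholds = qc_thresholds()) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown variant kind: ",
                                            paste(kind, collapse = "/")))
  s <- x$sites
  lt <- function(v, cut) !is.na(v) & v < cut
  gt <- function(v, cut) !is.na(v) & v > cut
  fail <- if (kind == "snp") {
    lt(s$qd, thresholds$snp_qd_min) |
      gt(s$fs, thresholds$snp_fs_max) |
      lt(s$mq, thresholds$snp_mq_min) |
      gt(s$sor, thresholds$snp_sor_max) |
      lt(s$mqranksum, thresholds$snp_mqranksum_min)
  } else {
    lt(s$qd, thresholds$indel_qd_min) |
      gt(s$fs, thresholds$indel_fs_max) |
      gt(s$sor, thresholds$indel_sor_max)
  }
  subset_sites(x, !fail)
}

# per-site minor allele frequency (second most frequent allele among
# non-missing diploid calls) and missing-call fraction
site_af_stats <- function(x) {
  idx <- gt_allele_indices(x$gt)
  k <- length(x$samples)
  n <- n_sites(x)
  maf <- numeric(n)
  miss <- numeric(n)
  for (i in seq_len(n)) {
    a <- c(idx$a1[i, ], idx$a2[i, ])
    a <- a[!is.na(a)]
    miss[i] <- (k - sum(!is.na(idx$a1[i, ]))) / k
    if (length(a) == 0L) {
      maf[i] <- 0
    } else {
      freq <- sort(tabulate(a + 1L) / length(a), decreasing = TRUE)
      maf[i] <- if (length(freq) > 1L) freq[2L] else 0
    }
  }
  list(maf = maf, missing = miss)
}

#' Filter on minor allele frequency and missing rate
#'
#' MAF is computed from non-missing diploid calls (allele counts over
#' 2 x non-missing samples); missing rate is the fraction of samples with a
#' missing genotype. Sites with MAF < `maf_min` or missing rate >
#' `missing_max` are removed; a site with no non-missing call falls under the
#' missing-rate rule.
#'
#' @inheritParams apply_hard_filters
#' @return the filtered `snp_table`
#' @export
filter_maf_missing <- function(x, thresholds = qc_thresholds()) {
  st <- site_af_stats(x)
  keep <- !(st$maf < thresholds$maf_min | st$missing > thresholds$missing_max)
  subset_sites(x, keep)
}

#' Filter on summed site depth
#'
#' Site depth is the sum of per-sample DP; a site is retained iff
#' `site_depth_low < depth < site_depth_high` (both bounds strict).
#'
#' @inheritParams apply_hard_filters
#' @return the filtered `snp_table`
#' @export
filter_site_depth <- function(x, thresholds = qc_thresholds()) {
  depth <- rowSums(x$dp)
  keep <- depth > thresholds$site_depth_low & depth < thresholds$site_depth_high
  subset_sites(x, keep)
}

#' Polymorphic-SNP screen
#'
#' Retains a site iff (1) every sample's depth exceeds
#' `per_sample_depth_min` (strict), (2) a valid genotype is present in every
#' sample, and (3) the most frequent genotype is carried by no more than
#' `identical_genotype_max_frac` of the samples.
#'
#' @inheritParams apply_hard_filters
#' @return the filtered `snp_table`
#' @export
polymorphic_screen <- function(x, thresholds = qc_thresholds()) {
  if (length(x$samples) < 2L) stop("polymorphic screen needs >= 2 samples")
  depth_ok <- rowSums(x$dp > thresholds$per_sample_depth_min) == length(x$samples)
  no_missing <- rowSums(is.na(x$gt)) == 0L
  modal_frac <- apply(x$gt, 1L, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(1)
    max(table(g)) / length(x$samples)
  })
  keep <- depth_ok & no_missing &
    modal_frac <= thresholds$identical_genotype_max_frac
  subset_sites(x, keep)
}

#' Run the full quality-control cascade
#'
#' Applies, in order, the hard filters, the MAF filter, the missing-rate
#' filter, and the summed site-depth window, recording the surviving record
#' count after each step (the order of the MAF and missing-rate steps is
#' configurable; each filter is idempotent so the final set is unaffected).
#'
#' @inheritParams apply_hard_filters
#' @param order character vector over `"maf"`, `"missing"`, `"depth"` giving
#'   the cascade order after the hard filters.
#' @return list with `table` (the filtered `snp_table`) and `report`
#'   (data.frame `filter`, `n_retained`)
#' @export
filter_cascade <- function(x, kind = "snp", thresholds = qc_thresholds(),
                           order = c("maf", "missing", "depth")) {
  stopifnot(all(order %in% c("maf", "missing", "depth")), !anyDuplicated(order))
  steps <- character(0)
  counts <- integer(0)
  cur <- apply_hard_filters(x, kind, thresholds)
  steps <- c(steps, "hard_filters"); counts <- c(counts, n_sites(cur))
  for (step in order) {
    cur <- switch(step,
      maf = {
        st <- site_af_stats(cur)
        subset_sites(cur, st$maf >= thresholds$maf_min)
      },
      missing = {
        st <- site_af_stats(cur)
        subset_sites(cur, st$missing <= thresholds$missing_max)
      },
      depth = filter_site_depth(cur, thresholds)
    )
    steps <- c(steps, step); counts <- c(counts, n_sites(cur))
  }
  list(table = cur,
       report = data.frame(filter = steps, n_retained = counts,
                           stringsAsFactors = FALSE))
}

#' Variant density in bases per variant
#'
#' The average spacing between variants on a chromosome, reported the way
#' genome-wide variant-rate tables print it: `floor(length / n_variants)`
#' bases per variant.
#'
#' @param chrom_length chromosome length in bp (vectorised).
#' @param n_variants variant count (vectorised, must be > 0).
#' @return integer bases-per-variant
#' @export
variant_density <- function(chrom_length, n_variants) {
  if (any(n_variants == 0)) stop("variant density undefined for 0 variants")
  as.integer(floor(chrom_length / n_variants))
}
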