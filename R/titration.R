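#' Binomially thin a haplotype count table to a target depth
#'
#' Emulates sequencing the same library at lower depth: each read is kept
#' independently with probability `target_depth / full_depth`, i.e. every
#' haplotype count is replaced by a Binomial(count, p) draw. Deterministic
#' under a fixed seed.
#'
#' @param counts a `count_table`.
#' @param target_depth,full_depth fold-coverage values, `target <= full`.
#' @param seed integer RNG seed.
#' @return the thinned `count_table`
#' @export
downsample_counts <- function(counts, target_depth, full_depth, seed) {
  if (target_depth > full_depth) {
    stop("contract error: target depth exceeds full depth")
  }
  p <- target_depth / full_depth
  set.seed(seed)
  entries <- lapply(counts$entries, function(cnt) {
    if (length(cnt) == 0L) return(cnt)
    structure(stats::rbinom(length(cnt), cnt, p), names = names(cnt))
  })
  count_table(counts$strain, entries)
}

#' Count genotype discordance between two profiles
#'
#' A marker is discordant when both calls are non-MISSING and the haplotype
#' sets differ; markers called in the reference but MISSING in the test
#' profile are tallied separately as newly missing, not as discordant.
#'
#' @param reference,test `mnp_profile` objects over the same markers.
#' @return list with `n_discordant`, `n_missing` and `n_total`
#' @export
count_discordant <- function(reference, test) {
  if (!identical(sort(names(reference$geno)), sort(names(test$geno)))) {
    stop("marker universe mismatch")
  }
  gt <- test$geno[names(reference$geno)]
  gr <- reference$geno
  both <- !is.na(gr) & !is.na(gt)
  list(
    n_discordant = sum(both & gr != gt),
    n_missing = sum(!is.na(gr) & is.na(gt)),
    n_total = length(gr)
  )
}

#' Depth-titration curve
#'
#' Re-genotypes binomially thinned copies of a deep count table at a grid of
#' target depths and counts markers whose call differs from the full-depth
#' profile. This is the in-silico analogue of sequencing one strain at
#' successively lower coverage to find the depth at which genotype calls
#' stabilise.
#'
#' @param counts_full deep `count_table`.
#' @param markers marker data.frame.
#' @param full_depth fold coverage of `counts_full`.
#' @param depths ascending vector of target depths.
#' @param reps independent thinning replicates per depth.
#' @param seed base RNG seed; replicate r at depth index d uses seed
#'   `seed + 1000*d + r` so runs are reproducible and replicates independent.
#' @param het_threshold,min_reads passed to [genotype_strain()].
#' @return data.frame in long format: `depth`, `replicate`, `n_discordant`,
#'   `n_missing`
#' @export
titration_curve <- function(counts_full, markers, full_depth, depths,
                            reps = 10L, seed = 1L,
                            het_threshold = 0.1, min_reads = 10L) {
  stopifnot(!is.unsorted(depths))
  reference <- genotype_strain(counts_full, markers, het_threshold, min_reads)
  rows <- list()
  for (d in seq_along(depths)) {
    for (r in seq_len(reps)) {
      thinned <- downsample_counts(counts_full, depths[d], full_depth,
                                   seed = seed + 1000L * d + r)
      prof <- genotype_strain(thinned, markers, het_threshold, min_reads)
      disc <- count_discordant(reference, prof)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = depths[d], replicate = r,
        n_discordant = disc$n_discordant,
        n_missing = disc$n_missing
      )
    }
  }
  do.call(rbind, rows)
}
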