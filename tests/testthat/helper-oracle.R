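# Independent brute-force reference for marker discovery and selection.
#
# Enumerates EVERY base-anchored 100-bp window that contains at least one
# SNP, collects each window's SNP set, keeps only subset-maximal sets (a
# base-anchored window's set is always contained in the set of the window
# anchored at its leftmost SNP, so the maximal sets are the complete
# candidate universe), dedupes identical sets keeping the leftmost SNP as
# start, then applies the count bounds, the PIC cutoff and the greedy
# left-to-right spacing rule by direct per-candidate iteration. Shares only
# compute_pic()/genotype_word() primitives with the package path.
oracle_select <- function(x, window = 100L, min_snps = 2L, max_snps = 10L,
                          pic_min = 0.5, spacing_bp = 50000L) {
  all_cands <- list()
  for (chr in unique(x$sites$chrom)) {
    rows <- which(x$sites$chrom == chr)
    pos <- x$sites$pos[rows]
    ranges <- list()
    for (p in pos) {
      for (b in (p - window + 1L):p) {   # every anchor whose window holds p
        inside <- which(pos >= b & pos <= b + window - 1L)
        key <- paste(inside, collapse = ",")
        ranges[[key]] <- inside
      }
    }
    # subset-maximality: drop any SNP set strictly contained in another
    keep <- vapply(seq_along(ranges), function(i) {
      !any(vapply(seq_along(ranges), function(j) {
        i != j && all(ranges[[i]] %in% ranges[[j]])
      }, logical(1L)))
    }, logical(1L))
    for (idx in ranges[keep]) {
      n <- length(idx)
      if (n < min_snps || n > max_snps) next
      words <- character(length(x$samples))
      for (s in seq_along(x$samples)) {
        words[s] <- genotype_word(x$gt[rows[idx], s])
      }
      tab <- table(words)
      freqs <- structure(as.numeric(tab) / length(words), names = names(tab))
      all_cands[[length(all_cands) + 1L]] <- list(
        chrom = chr, start = pos[idx[1L]],
        snp_positions = pos[idx],
        pic = compute_pic(freqs)
      )
    }
  }
  if (length(all_cands) == 0L) return(data.frame())
  df <- data.frame(
    chrom = vapply(all_cands, `[[`, character(1L), "chrom"),
    start = vapply(all_cands, `[[`, integer(1L), "start"),
    pic = vapply(all_cands, `[[`, numeric(1L), "pic"),
    stringsAsFactors = FALSE
  )
  df$snp_positions <- lapply(all_cands, `[[`, "snp_positions")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df <- df[df$pic >= pic_min, , drop = FALSE]
  # greedy spacing, one candidate at a time
  accepted <- integer(0)
  last <- list()
  for (i in seq_len(nrow(df))) {
    chr <- df$chrom[i]
    if (is.null(last[[chr]]) || df$start[i] - last[[chr]] > spacing_bp) {
      accepted <- c(accepted, i)
      last[[chr]] <- df$start[i]
    }
  }
  out <- df[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random small population for oracle comparisons: a few chroms, mixed
# cluster/singleton geometry so window overlaps and spacing conflicts occur
oracle_instance <- function(seed, n_samples = 6L, n_chrom = 2L,
                            n_snps_per_chrom = 60L, span = 300000L) {
  set.seed(seed)
  tabs <- list()
  for (c_i in seq_len(n_chrom)) {
    pos <- sort(sample.int(span, n_snps_per_chrom))
    pos <- unique(pos)
    gt <- matrix("0/0", length(pos), n_samples)
    for (i in seq_along(pos)) {
      p <- runif(1, 0.2, 0.8)
      a1 <- rbinom(n_samples, 1, p)
      a2 <- rbinom(n_samples, 1, p)
      gt[i, ] <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
    }
    tabs[[c_i]] <- make_table(sprintf("c%d", c_i), pos, gt)
  }
  sites <- do.call(rbind, lapply(tabs, function(t) t$sites))
  gt <- do.call(rbind, lapply(tabs, function(t) t$gt))
  dp <- do.call(rbind, lapply(tabs, function(t) t$dp))
  snp_table(sites, gt, dp, tabs[[1L]]$samples)
}
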