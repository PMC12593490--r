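#' Canonical window genotype word for one sample
#'
#' Encodes a sample's diploid calls at the SNPs of one window as a single
#' comparable string: homozygous reference is `"R"`, homozygous for alternate
#' allele k is `"k"`, and a heterozygote is the sorted allele-index pair
#' (e.g. `"01"`); per-SNP tokens are joined with `"|"`. `(1,0)` and `(0,1)`
#' therefore encode identically.
#'
#' @param gts character vector of `"a/b"` genotype strings, one per window
#'   SNP, none missing (guaranteed upstream by [polymorphic_screen()]).
#' @return single string
#' @export
genotype_word <- function(gts) {
  if (any(is.na(gts))) {
    stop("contract error: missing genotype inside a marker window")
  }
  a1 <- as.integer(sub("/.*$", "", gts))
  a2 <- as.integer(sub("^.*/", "", gts))
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  tok <- ifelse(lo == hi,
                ifelse(lo == 0L, "R", as.character(lo)),
                paste0(lo, hi))
  paste(tok, collapse = "|")
}

#' Polymorphism information content of a marker
#'
#' Measures how informative a marker's genotype-word distribution is. The
#' default is Nei's gene diversity, `1 - sum(p_i^2)`; `mode = "botstein"`
#' additionally subtracts the double-heterozygote term
#' `sum_i sum_{j>i} 2 p_i^2 p_j^2`.
#'
#' @param freqs named numeric vector of word frequencies summing to 1.
#' @param mode `"gene_diversity"` (default) or `"botstein"`.
#' @return PIC value in `[0, 1)`
#' @export
compute_pic <- function(freqs, mode = c("gene_diversity", "botstein")) {
  mode <- match.arg(mode)
  if (any(freqs < 0)) stop("contract error: negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  base <- 1 - sum(freqs^2)
  if (mode == "gene_diversity") return(base)
  # sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  p2 <- freqs^2
  base - (sum(p2)^2 - sum(p2^2))
}

# genotype words for rows i..j of the table, one word per sample
window_words <- function(x, i, j) {
  apply(x$gt[i:j, , drop = FALSE], 2L, genotype_word)
}

#' Scan a filtered callset with fixed-width windows
#'
#' Anchors one window `[p, p + window - 1]` at each SNP position `p`, keeps
#' windows containing between `min_snps` and `max_snps` SNPs, deduplicates
#' identical SNP sets keeping the leftmost start, and scores each candidate
#' by the PIC of its genotype-word distribution across all samples.
#'
#' @param x a `snp_table` that already passed [polymorphic_screen()].
#' @param window window width in bp.
#' @param min_snps,max_snps inclusive bounds on SNPs per window.
#' @param pic_mode passed to [compute_pic()].
#' @return data.frame of candidates: `chrom`, `start`, `end`, `n_snps`,
#'   `pic`, plus list columns `snp_positions` and `words` (named frequency
#'   vectors)
#' @export
scan_windows <- function(x, window = 100L, min_snps = 2L, max_snps = 10L,
                         pic_mode = "gene_diversity") {
  out <- list()
  for (chr in unique(x$sites$chrom)) {
    rows <- which(x$sites$chrom == chr)
    pos <- x$sites$pos[rows]
    # index of last SNP inside each anchored window
    j_rel <- findInterval(pos + window - 1L, pos)
    n_in <- j_rel - seq_along(pos) + 1L
    keep <- n_in >= min_snps & n_in <= max_snps
    for (i_rel in which(keep)) {
      i <- rows[i_rel]; j <- rows[j_rel[i_rel]]
      words <- window_words(x, i, j)
      freqs <- table(words) / length(words)
      freqs <- structure(as.numeric(freqs), names = names(freqs))
      out[[length(out) + 1L]] <- list(
        chrom = chr, start = pos[i_rel], end = pos[i_rel] + window - 1L,
        n_snps = n_in[i_rel],
        snp_positions = x$sites$pos[i:j],
        pic = compute_pic(freqs, pic_mode),
        words = freqs
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(), pic = numeric()))
  }
  cands <- data.frame(
    chrom = vapply(out, `[[`, character(1L), "chrom"),
    start = vapply(out, `[[`, integer(1L), "start"),
    end = vapply(out, `[[`, integer(1L), "end"),
    n_snps = vapply(out, `[[`, integer(1L), "n_snps"),
    pic = vapply(out, `[[`, numeric(1L), "pic"),
    stringsAsFactors = FALSE
  )
  cands$snp_positions <- lapply(out, `[[`, "snp_positions")
  cands$words <- lapply(out, `[[`, "words")
  # dedupe identical SNP sets, keeping leftmost start (SNP anchoring makes
  # sets unique already, but the contract is explicit)
  key <- paste(cands$chrom,
               vapply(cands$snp_positions, paste, character(1L), collapse = ","))
  cands <- cands[order(cands$chrom, cands$start), , drop = FALSE]
  cands <- cands[!duplicated(key[order(cands$chrom, cands$start)]), , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Select MNP markers from window candidates
#'
#' Drops candidates below the PIC cutoff, then greedily accepts candidates
#' left-to-right within each chromosome whenever the start exceeds the last
#' accepted start by strictly more than `spacing_bp` (the first candidate on a
#' chromosome is always accepted). Stable ids `mnp_0001`, `mnp_0002`, ... are
#' assigned in genomic order.
#'
#' @param candidates output of [scan_windows()].
#' @param pic_min inclusive PIC cutoff.
#' @param spacing_bp minimum start-to-start distance (strict) between
#'   accepted markers on one chromosome.
#' @param rank_by_pic if `TRUE`, candidates are considered in decreasing-PIC
#'   order instead of left-to-right (spacing enforced against all previously
#'   accepted markers); off by default.
#' @return data.frame of markers with a leading `marker_id` column
#' @export
select_markers <- function(candidates, pic_min = 0.5, spacing_bp = 50000L,
                           rank_by_pic = FALSE) {
  cands <- candidates[candidates$pic >= pic_min, , drop = FALSE]
  if (nrow(cands) == 0L) {
    cands$marker_id <- character(0)
    return(cands[, c("marker_id", setdiff(names(cands), "marker_id"))])
  }
  accepted <- logical(nrow(cands))
  if (!rank_by_pic) {
    ord <- order(cands$chrom, cands$start)
    last_start <- list()
    for (i in ord) {
      chr <- cands$chrom[i]
      if (is.null(last_start[[chr]]) ||
          cands$start[i] - last_start[[chr]] > spacing_bp) {
        accepted[i] <- TRUE
        last_start[[chr]] <- cands$start[i]
      }
    }
  } else {
    ord <- order(-cands$pic, cands$chrom, cands$start)
    taken <- list()
    for (i in ord) {
      chr <- cands$chrom[i]
      prev <- taken[[chr]]
      if (is.null(prev) || all(abs(prev - cands$start[i]) > spacing_bp)) {
        accepted[i] <- TRUE
        taken[[chr]] <- c(prev, cands$start[i])
      }
    }
  }
  sel <- cands[accepted, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), , drop = FALSE]
  sel$marker_id <- sprintf("mnp_%04d", seq_len(nrow(sel)))
  rownames(sel) <- NULL
  canonical <- c("marker_id", "chrom", "start", "end", "n_snps",
                 "snp_positions", "pic")
  sel[, c(canonical, setdiff(names(sel), canonical))]
}

#' Write a marker table to TSV
#'
#' @param markers marker data.frame from [select_markers()].
#' @param path output TSV with columns `marker_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_snps`, `snp_positions` (comma-joined), `pic`.
#' @return `path`, invisibly
#' @export
write_marker_table <- function(markers, path) {
  if (nrow(markers) == 0L) stop("refusing to write an empty marker table")
  df <- data.frame(
    marker_id = markers$marker_id,
    chrom = markers$chrom,
    start = markers$start,
    end = markers$end,
    n_snps = markers$n_snps,
    snp_positions = vapply(markers$snp_positions, paste,
                           character(1L), collapse = ","),
    pic = markers$pic,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#'
#' @param path TSV file.
#' @return marker data.frame with `snp_positions` as a list column
#' @export
read_marker_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$snp_positions <- lapply(strsplit(as.character(df$snp_positions), ","),
                             as.integer)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$n_snps <- as.integer(df$n_snps)
  df
}
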