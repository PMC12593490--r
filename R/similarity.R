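# half-away-from-zero rounding; base round() rounds half to even, which does
# not reproduce printed GS values such as 255/369 -> 69.11
round_half_up <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Pairwise genetic similarity of two strains
#'
#' GS(%) = n/N x 100, where n is the number of MNP markers at which the two
#' strains carry identical genotypes (exact haplotype-set equality: a
#' heterozygote matches only the same unordered pair) and N the number of
#' markers compared. With `mode = "total"` (default) N is the full database
#' marker count and a marker MISSING in either strain counts as a non-match;
#' with `mode = "shared"` N is the number of markers non-MISSING in both.
#' GS is rounded half-away-from-zero to two decimals.
#'
#' @param a,b `mnp_profile` objects over the same marker universe.
#' @param mode `"total"` or `"shared"`.
#' @return list of class `gs_result`: `strain_a`, `strain_b`, `n`, `N`, `gs`
#' @export
compute_gs <- function(a, b, mode = c("total", "shared")) {
  mode <- match.arg(mode)
  if (!identical(sort(names(a$geno)), sort(names(b$geno)))) {
    stop("contract error: profiles have different marker universes")
  }
  gb <- b$geno[names(a$geno)]
  ga <- a$geno
  both <- !is.na(ga) & !is.na(gb)
  n <- sum(both & ga == gb, na.rm = TRUE)
  N <- if (mode == "total") length(ga) else sum(both)
  if (N == 0L) stop("no markers to compare (all MISSING in one strain)")
  structure(list(strain_a = a$strain, strain_b = b$strain,
                 n = as.integer(n), N = as.integer(N),
                 gs = round_half_up(100 * n / N, 2L)),
            class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("GS(%s, %s) = %.2f%%  (n = %d of N = %d markers)\n",
              x$strain_a, x$strain_b, x$gs, x$n, x$N))
  invisible(x)
}

#' All pairwise genetic similarities in a database
#'
#' Computes GS for every unordered strain pair once, mirrors it, and sets the
#' diagonal to 100.00.
#'
#' @param db an `mnp_db` with at least two strain profiles.
#' @inheritParams compute_gs
#' @return object of class `gs_matrix`: list with `strains`, `gs` (numeric
#'   matrix, %), `n` and `N` (integer matrices of match and comparison
#'   counts)
#' @export
gs_matrix <- function(db, mode = c("total", "shared")) {
  mode <- match.arg(mode)
  strains <- names(db$profiles)
  k <- length(strains)
  if (k < 2L) stop("contract error: need >= 2 strains")
  gs <- matrix(100, k, k, dimnames = list(strains, strains))
  nm <- matrix(0L, k, k, dimnames = list(strains, strains))
  Nm <- matrix(nrow(db$markers), k, k, dimnames = list(strains, strains))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- compute_gs(db$profiles[[i]], db$profiles[[j]], mode)
      gs[i, j] <- gs[j, i] <- r$gs
      nm[i, j] <- nm[j, i] <- r$n
      Nm[i, j] <- Nm[j, i] <- r$N
    }
  }
  diag(nm) <- diag(Nm)
  structure(list(strains = strains, gs = gs, n = nm, N = Nm,
                 mode = mode), class = "gs_matrix")
}

#' @export
print.gs_matrix <- function(x, ...) {
  off <- x$gs[upper.tri(x$gs)]
  cat(sprintf("gs_matrix: %d strains, %d pairs, GS %.2f-%.2f%% (mode=%s)\n",
              length(x$strains), length(off), min(off), max(off), x$mode))
  invisible(x)
}

#' Classify a strain pair at the identity threshold
#'
#' Varieties with GS at or above the threshold are treated as highly similar
#' or identical; below it, as distinct. The default 99% reflects the near-
#' clonal propagation of cultivated fungi, where true re-isolates of one
#' variety differ only by rare mutation.
#'
#' @param gs GS percentage in `[0, 100]`.
#' @param identity_threshold inclusive threshold (%).
#' @return `"identical"` or `"distinct"` (vectorised)
#' @export
classify_pair <- function(gs, identity_threshold = 99.0) {
  if (any(gs < 0 | gs > 100)) stop("contract error: GS outside [0, 100]")
  ifelse(gs >= identity_threshold, "identical", "distinct")
}

#' Hierarchically cluster strains from a GS matrix
#'
#' Converts similarity to distance `d = 1 - gs/100` and runs agglomerative
#' clustering. The tree can be exported with [write_newick()]; the leaf order
#' is what a fingerprint heatmap would use.
#'
#' @param m a `gs_matrix`.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`, i.e. UPGMA).
#' @return list with `hclust`, `phylo` (ape tree) and `order` (leaf labels)
#' @export
cluster_gs <- function(m, linkage = "average") {
  stopifnot(inherits(m, "gs_matrix"))
  if (!isTRUE(all.equal(m$gs, t(m$gs)))) {
    stop("contract error: GS matrix is not symmetric")
  }
  d <- stats::as.dist(1 - m$gs / 100)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, phylo = ape::as.phylo(hc), order = hc$labels[hc$order])
}

#' Summarise GS ranges within and between strain groups
#'
#' @param m a `gs_matrix`.
#' @param groups named character vector mapping every strain to a group label
#'   (e.g. fruit-body colour).
#' @return data.frame with one row per group pair (within-group rows have
#'   `group_a == group_b`): `n_pairs`, `min`, `max`, `mean` of off-diagonal
#'   GS
#' @export
summarize_ranges <- function(m, groups) {
  stopifnot(inherits(m, "gs_matrix"))
  unknown <- setdiff(names(groups), m$strains)
  if (length(unknown) > 0L) stop("unknown strain in groups: ", unknown[1L])
  if (!all(m$strains %in% names(groups))) {
    stop("every strain must be labelled; missing: ",
         paste(setdiff(m$strains, names(groups)), collapse = ", "))
  }
  labels <- sort(unique(groups))
  empty <- setdiff(labels, unique(groups[m$strains]))
  if (length(empty) > 0L) warning("empty group(s): ", paste(empty, collapse = ", "))
  out <- list()
  for (ia in seq_along(labels)) {
    for (ib in ia:length(labels)) {
      ga <- m$strains[groups[m$strains] == labels[ia]]
      gb <- m$strains[groups[m$strains] == labels[ib]]
      vals <- if (labels[ia] == labels[ib]) {
        sub <- m$gs[ga, gb, drop = FALSE]
        sub[upper.tri(sub)]
      } else {
        as.vector(m$gs[ga, gb, drop = FALSE])
      }
      if (length(vals) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        group_a = labels[ia], group_b = labels[ib],
        n_pairs = length(vals),
        min = min(vals), max = max(vals),
        mean = round_half_up(mean(vals), 2L),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
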