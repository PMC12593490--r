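#' Simulation configuration for a synthetic strain population
#'
#' Defines a population of dikaryotic fungal strains with two colour
#' subpopulations, optional F1 hybrid trios and clonal duplicates, from which
#' a multi-sample SNP callset, haplotype read counts and ISSR band matrices
#' can be generated with known truth.
#'
#' Two SNP layouts are supported. `"clustered"` (default) places tight 2-5
#' SNP clusters separated by more than the marker spacing, so each cluster
#' corresponds 1:1 to one discoverable MNP marker — this gives exact truth
#' for recovery experiments. `"poisson"` scatters SNPs uniformly at
#' `snp_density`, which reproduces genome-wide SNP-count scaling.
#'
#' The defaults emulate the study population this package targets: 32 strains
#' (18 white, 14 gray), 12 chromosomes, roughly 370 marker clusters averaging
#' ~3.4 SNPs each, 60-fold coverage.
#'
#' @param n_strains number of strains.
#' @param group_labels named integer vector of strains per group.
#' @param n_chroms number of chromosomes.
#' @param layout `"clustered"` or `"poisson"`.
#' @param n_clusters_per_chrom clusters per chromosome (clustered layout).
#' @param cluster_spacing_bp distance between cluster starts; must exceed the
#'   marker spacing rule (50 kb) plus the window width.
#' @param snps_per_cluster integer range to draw each cluster's SNP count
#'   from.
#' @param chrom_length_bp chromosome length (poisson layout; clustered layout
#'   derives it from the cluster grid).
#' @param snp_density SNPs per bp (poisson layout).
#' @param divergence between-group allele-frequency divergence (Wright's Fst
#'   in the Balding-Nichols sense).
#' @param het_rate probability that a strain's two nuclear alleles are drawn
#'   independently from the group frequency; `1 - het_rate` is the excess
#'   homozygosity of clonal propagation.
#' @param hybrid_trios list of `list(parents = c(a, b), children = c(...))`;
#'   children are Mendelian F1 draws from the named parents.
#' @param clone_pairs list of `c(copy, source)` pairs; the copy strain gets
#'   the source's genotypes verbatim.
#' @param marker_sharing_targets list of `list(a, b, f)`: after marker
#'   discovery, strain `b`'s marker genotypes are overwritten so the pair
#'   agrees at exactly `round(f * n_markers)` markers (see
#'   [apply_sharing_targets()]).
#' @param depth read depth (fold coverage) for count simulation.
#' @param error_rate per-base sequencing error rate.
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_strains = 32L,
                       group_labels = c(white = 18L, gray = 14L),
                       n_chroms = 12L,
                       layout = c("clustered", "poisson"),
                       n_clusters_per_chrom = 31L,
                       cluster_spacing_bp = 60000L,
                       snps_per_cluster = 2:5,
                       chrom_length_bp = 2e6,
                       snp_density = 1 / 104,
                       divergence = 0.25,
                       het_rate = 0.9,
                       hybrid_trios = list(),
                       clone_pairs = list(),
                       marker_sharing_targets = list(),
                       depth = 60,
                       error_rate = 0.001,
                       seed = NULL) {
  layout <- match.arg(layout)
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  stopifnot(sum(group_labels) == n_strains,
            het_rate >= 0, het_rate <= 1,
            divergence > 0, divergence < 1,
            error_rate >= 0, error_rate < 1,
            cluster_spacing_bp > 50100L)
  structure(as.list(environment()), class = "sim_config")
}

# Balding-Nichols draw of a group allele frequency around ancestral p
bn_freq <- function(p, fst) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  pmin(pmax(stats::rbeta(length(p), a, b), 0.03), 0.97)
}

#' Simulate a strain population with known truth
#'
#' Generates phased per-strain genotypes at simulated SNPs plus the
#' multi-sample `snp_table` a variant caller would have produced (constant
#' high-confidence INFO annotations, Poisson per-sample depths around
#' `cfg$depth`). Hybrid children are drawn per SNP cluster: one whole-cluster
#' haplotype from each parent, independently across clusters. Clone strains
#' copy their source verbatim.
#'
#' @param cfg a [sim_config()].
#' @return list with `truth` (class `sim_truth`: strain phased haplotype
#'   matrices, SNP map with cluster ids, pedigree, clone map, config) and
#'   `table` (a `snp_table`)
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  strains <- sprintf("S%02d", seq_len(cfg$n_strains))
  groups <- rep(names(cfg$group_labels), cfg$group_labels)
  names(groups) <- strains

  # --- SNP map -------------------------------------------------------------
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chroms))
  map <- list()
  for (c_i in seq_along(chroms)) {
    if (cfg$layout == "clustered") {
      starts <- 1L + (seq_len(cfg$n_clusters_per_chrom) - 1L) * cfg$cluster_spacing_bp
      for (k in seq_along(starts)) {
        n <- sample(cfg$snps_per_cluster, 1L)
        off <- sort(sample(0:99, n))
        map[[length(map) + 1L]] <- data.frame(
          chrom = chroms[c_i], pos = starts[k] + off,
          cluster = paste0(chroms[c_i], "_c", k))
      }
    } else {
      n <- stats::rpois(1L, cfg$chrom_length_bp * cfg$snp_density)
      pos <- sort(sample.int(cfg$chrom_length_bp, min(n, cfg$chrom_length_bp)))
      if (length(pos) > 0L) {
        map[[length(map) + 1L]] <- data.frame(
          chrom = chroms[c_i], pos = pos,
          cluster = paste0(chroms[c_i], "_s", seq_along(pos)))
      }
    }
  }
  map <- do.call(rbind, map)
  n_snp <- nrow(map)
  if (n_snp == 0L) stop("no SNPs simulated; increase density or clusters")
  has_pair <- any(unlist(tapply(map$pos, map$chrom,
                                function(p) diff(p) <= 99L)))
  if (!has_pair) {
    stop("SNP density too low: no 100-bp window holds 2 SNPs")
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))

  # --- group allele frequencies -------------------------------------------
  p_anc <- stats::runif(n_snp, 0.15, 0.85)
  p_group <- vapply(names(cfg$group_labels), function(g) bn_freq(p_anc, cfg$divergence),
                    numeric(n_snp))
  if (is.null(dim(p_group))) p_group <- matrix(p_group, nrow = n_snp)
  colnames(p_group) <- names(cfg$group_labels)

  # --- base strain haplotypes ---------------------------------------------
  hap1 <- matrix(0L, n_snp, cfg$n_strains, dimnames = list(NULL, strains))
  hap2 <- hap1
  for (s in strains) {
    p <- p_group[, groups[[s]]]
    h1 <- stats::rbinom(n_snp, 1L, p)
    indep <- stats::runif(n_snp) < cfg$het_rate
    h2 <- ifelse(indep, stats::rbinom(n_snp, 1L, p), h1)
    hap1[, s] <- h1
    hap2[, s] <- h2
  }

  truth <- structure(list(
    strains = strains, groups = groups, map = map,
    ref = ref, alt = alt, hap1 = hap1, hap2 = hap2,
    pedigree = list(), clones = character(0), cfg = cfg
  ), class = "sim_truth")

  # --- hybrids and clones --------------------------------------------------
  for (trio in cfg$hybrid_trios) {
    for (child in trio$children) {
      h <- simulate_hybrid(truth, trio$parents[1L], trio$parents[2L],
                           seed = NULL)
      truth$hap1[, child] <- h$hap1
      truth$hap2[, child] <- h$hap2
      truth$pedigree[[child]] <- trio$parents
    }
  }
  for (pair in cfg$clone_pairs) {
    copy <- pair[1L]; source <- pair[2L]
    if (!all(c(copy, source) %in% strains)) stop("unknown strain in clone pair")
    truth$hap1[, copy] <- truth$hap1[, source]
    truth$hap2[, copy] <- truth$hap2[, source]
    truth$clones[copy] <- source
  }

  list(truth = truth, table = truth_to_snp_table(truth))
}

#' Draw an F1 hybrid from two parent strains
#'
#' For each SNP cluster the child inherits one whole-cluster haplotype from
#' each parent (which of the parent's two is drawn uniformly, independently
#' across clusters) — Mendelian sampling with complete linkage inside a
#' marker window and free recombination between markers.
#'
#' @param truth a `sim_truth`.
#' @param parent_a,parent_b strain ids present in `truth`.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @return list with integer vectors `hap1`, `hap2`
#' @export
simulate_hybrid <- function(truth, parent_a, parent_b, seed = NULL) {
  if (!all(c(parent_a, parent_b) %in% truth$strains)) {
    stop("unknown parent strain")
  }
  if (!is.null(seed)) set.seed(seed)
  cl <- truth$map$cluster
  cl_ids <- unique(cl)
  pick_a <- sample(c(TRUE, FALSE), length(cl_ids), replace = TRUE)
  pick_b <- sample(c(TRUE, FALSE), length(cl_ids), replace = TRUE)
  names(pick_a) <- names(pick_b) <- cl_ids
  from_a <- ifelse(pick_a[cl], truth$hap1[, parent_a], truth$hap2[, parent_a])
  from_b <- ifelse(pick_b[cl], truth$hap1[, parent_b], truth$hap2[, parent_b])
  list(hap1 = as.integer(from_a), hap2 = as.integer(from_b))
}

# materialise the snp_table a variant caller would emit for the truth
truth_to_snp_table <- function(truth) {
  n_snp <- nrow(truth$map)
  k <- length(truth$strains)
  lo <- pmin(truth$hap1, truth$hap2)
  hi <- pmax(truth$hap1, truth$hap2)
  gt <- matrix(paste0(lo, "/", hi), n_snp, k)
  dp <- matrix(stats::rpois(n_snp * k, truth$cfg$depth), n_snp, k)
  storage.mode(dp) <- "integer"
  sites <- data.frame(
    chrom = truth$map$chrom, pos = truth$map$pos,
    ref = truth$ref, alt = truth$alt,
    qd = round(stats::runif(n_snp, 20, 35), 2),
    fs = round(stats::runif(n_snp, 0, 5), 3),
    mq = round(stats::runif(n_snp, 55, 60), 2),
    sor = round(stats::runif(n_snp, 0.4, 1.5), 3),
    mqranksum = round(stats::runif(n_snp, -1.5, 1.5), 3),
    stringsAsFactors = FALSE
  )
  snp_table(sites, gt, dp, truth$strains)
}

#' Per-strain true marker haplotypes
#'
#' Projects the phased SNP-level truth onto a set of discovered markers: for
#' each marker and strain, the two window haplotype strings are the bases
#' carried at the marker's SNP positions.
#'
#' @param truth a `sim_truth`.
#' @param markers marker data.frame from [select_markers()] run on the
#'   simulated callset.
#' @return object of class `marker_truth`: `marker_ids`, `strains`, and
#'   string matrices `h1`, `h2` (markers x strains)
#' @export
derive_marker_truth <- function(truth, markers) {
  key <- paste(truth$map$chrom, truth$map$pos)
  h1 <- matrix(NA_character_, nrow(markers), length(truth$strains),
               dimnames = list(markers$marker_id, truth$strains))
  h2 <- h1
  for (i in seq_len(nrow(markers))) {
    rows <- match(paste(markers$chrom[i], markers$snp_positions[[i]]), key)
    if (anyNA(rows)) stop("marker SNP position not found in truth")
    b1 <- ifelse(truth$hap1[rows, , drop = FALSE] == 1L, truth$alt[rows],
                 truth$ref[rows])
    b2 <- ifelse(truth$hap2[rows, , drop = FALSE] == 1L, truth$alt[rows],
                 truth$ref[rows])
    h1[i, ] <- apply(matrix(b1, nrow = length(rows)), 2L, paste, collapse = "")
    h2[i, ] <- apply(matrix(b2, nrow = length(rows)), 2L, paste, collapse = "")
  }
  structure(list(marker_ids = markers$marker_id, strains = truth$strains,
                 h1 = h1, h2 = h2), class = "marker_truth")
}

# canonical truth genotype string at marker i, strain s
truth_genotype <- function(mt, i, s) {
  paste(sort(unique(c(mt$h1[i, s], mt$h2[i, s]))), collapse = "/")
}

#' Engineer exact marker-sharing fractions between strain pairs
#'
#' For each target `list(a, b, f)`, strain `b`'s haplotypes are overwritten
#' with `a`'s at exactly `round(f * n_markers)` randomly chosen markers; at
#' every remaining marker where the two genotypes coincide by chance, `b`'s
#' first haplotype is resampled to a distinct string, so the pair agrees at
#' exactly the engineered marker set. This gives exact ground truth for
#' genetic-similarity recovery experiments.
#'
#' @param mt a `marker_truth`.
#' @param targets list of `list(a = strain, b = strain, f = fraction)`.
#' @param seed RNG seed.
#' @return the modified `marker_truth`, with an `engineered` attribute
#'   recording each pair's exact shared-marker count
#' @export
apply_sharing_targets <- function(mt, targets, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  record <- list()
  for (tg in targets) {
    a <- tg$a; b <- tg$b; f <- tg$f
    if (!all(c(a, b) %in% mt$strains)) stop("unknown strain in sharing target")
    K <- length(mt$marker_ids)
    n_share <- round(f * K)
    share_idx <- sort(sample.int(K, n_share))
    mt$h1[share_idx, b] <- mt$h1[share_idx, a]
    mt$h2[share_idx, b] <- mt$h2[share_idx, a]
    for (i in setdiff(seq_len(K), share_idx)) {
      if (truth_genotype(mt, i, a) == truth_genotype(mt, i, b)) {
        h <- mt$h1[i, b]
        taken <- substr(c(mt$h1[i, a], mt$h2[i, a], mt$h2[i, b]), 1L, 1L)
        substr(h, 1L, 1L) <- sample(setdiff(bases, taken), 1L)
        mt$h1[i, b] <- h
      }
    }
    record[[paste(a, b, sep = ":")]] <- list(a = a, b = b, f = f,
                                             n_shared = n_share, N = K)
  }
  attr(mt, "engineered") <- record
  mt
}

#' Simulate haplotype read counts from marker truth
#'
#' Per strain and marker the total read count is Poisson(`depth`); each read
#' is drawn from the strain's two true haplotypes with equal probability
#' (both nuclei contribute equally in a dikaryon), and every base is flipped
#' to a uniformly chosen other base with probability `error_rate`, producing
#' off-target haplotype strings.
#'
#' @param mt a `marker_truth`.
#' @param depth fold coverage.
#' @param error_rate per-base error probability.
#' @param seed RNG seed.
#' @return named list of `count_table`, one per strain
#' @export
simulate_counts <- function(mt, depth, error_rate = 0, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- lapply(mt$strains, function(s) {
    entries <- lapply(seq_along(mt$marker_ids), function(i) {
      tot <- stats::rpois(1L, depth)
      if (tot == 0L) return(structure(integer(0), names = character(0)))
      k1 <- stats::rbinom(1L, tot, 0.5)
      reads <- c(rep(mt$h1[i, s], k1), rep(mt$h2[i, s], tot - k1))
      if (error_rate > 0) {
        L <- nchar(reads[1L])
        rm_ <- matrix(stats::runif(tot * L) < error_rate, tot, L)
        if (any(rm_)) {
          chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                          nrow = tot, byrow = TRUE)
          idx <- which(rm_, arr.ind = TRUE)
          for (r in seq_len(nrow(idx))) {
            cur <- chars[idx[r, 1L], idx[r, 2L]]
            chars[idx[r, 1L], idx[r, 2L]] <- sample(setdiff(bases, cur), 1L)
          }
          reads <- apply(chars, 1L, paste, collapse = "")
        }
      }
      tab <- table(reads)
      structure(as.integer(tab), names = names(tab))
    })
    names(entries) <- mt$marker_ids
    count_table(s, entries)
  })
  names(out) <- mt$strains
  out
}

#' Simulate a block-structured ISSR band matrix
#'
#' Each group receives a block of characteristic bands present with high
#' probability inside the group and low probability outside, plus a set of
#' near-universal bands shared by all strains — the pattern a small panel of
#' informative ISSR primers produces on a structured population.
#'
#' @param groups named character vector strain -> group label.
#' @param bands_per_group characteristic bands per group.
#' @param n_shared near-universal background bands.
#' @param p_within,p_outside presence probabilities inside/outside the
#'   band's home group.
#' @param n_primers number of primers the bands are attributed to (bands are
#'   dealt round-robin).
#' @param seed RNG seed.
#' @return a `band_matrix`
#' @export
simulate_bands <- function(groups, bands_per_group = 8L, n_shared = 4L,
                           p_within = 0.92, p_outside = 0.05,
                           n_primers = 10L, seed = 1L) {
  set.seed(seed)
  strains <- names(groups)
  labels <- unique(groups)
  band_ids <- character(0)
  cols <- list()
  for (g in labels) {
    for (b in seq_len(bands_per_group)) {
      p <- ifelse(groups == g, p_within, p_outside)
      cols[[length(cols) + 1L]] <- stats::rbinom(length(strains), 1L, p)
      band_ids <- c(band_ids, paste0("band_", g, "_", b))
    }
  }
  for (b in seq_len(n_shared)) {
    cols[[length(cols) + 1L]] <- stats::rbinom(length(strains), 1L, 0.97)
    band_ids <- c(band_ids, paste0("band_shared_", b))
  }
  values <- do.call(cbind, cols)
  dimnames(values) <- list(strains, band_ids)
  primers <- structure(paste0("P", sprintf("%02d", rep_len(seq_len(n_primers),
                                                           length(band_ids)))),
                       names = band_ids)
  suppressWarnings(band_matrix(values, primers))
}

#' Simulate the ISSR band pattern of an F1 offspring
#'
#' The child inherits the union of its parents' bands, each independently
#' lost with probability `dropout` (a segregating dominant band is absent
#' when the child inherits neither parental allele).
#'
#' @param m a `band_matrix` containing both parents.
#' @param parent_a,parent_b,child strain ids; `child` is appended.
#' @param dropout per-band loss probability.
#' @param seed RNG seed.
#' @return the extended `band_matrix`
#' @export
simulate_band_offspring <- function(m, parent_a, parent_b, child,
                                    dropout = 0.15, seed = 1L) {
  stopifnot(all(c(parent_a, parent_b) %in% rownames(m$values)))
  set.seed(seed)
  un <- as.integer(m$values[parent_a, ] | m$values[parent_b, ])
  keep <- stats::rbinom(length(un), 1L, 1 - dropout)
  values <- rbind(m$values, un * keep)
  rownames(values)[nrow(values)] <- child
  suppressWarnings(band_matrix(values, m$primer_of_band))
}
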