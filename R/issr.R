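#' Construct an ISSR band matrix
#'
#' Presence/absence fingerprint: rows are strains, columns are scored bands
#' (primer x size-bin), entries 1 for a clear band and 0 for none. Bands
#' present in more than 95% or fewer than 5% of strains carry almost no
#' information and are flagged with a warning.
#'
#' @param values binary matrix with strain rownames and band-id colnames.
#' @param primer_of_band named character vector mapping each band id to its
#'   primer (optional; needed by [band_summary()]).
#' @return object of class `band_matrix`
#' @export
band_matrix <- function(values, primer_of_band = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) stop("band matrix entries must be 0/1")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("band matrix needs unique strain rownames")
  }
  storage.mode(values) <- "integer"
  prev <- colMeans(values)
  dull <- colnames(values)[prev > 0.95 | prev < 0.05]
  if (length(dull) > 0L) {
    warning("uninformative bands (present in >95% or <5% of strains): ",
            paste(utils::head(dull, 5L), collapse = ", "))
  }
  structure(list(values = values, primer_of_band = primer_of_band),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d strains x %d bands\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a 0/1 band matrix from TSV
#'
#' First column holds strain ids; remaining columns are band ids. An optional
#' comment line `#primer<TAB><band>=<primer>,...` carries the band-to-primer
#' mapping.
#'
#' @param path TSV file.
#' @return a `band_matrix`
#' @export
read_band_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  primer_map <- NULL
  if (startsWith(first, "#primer")) {
    spec <- sub("^#primer\t", "", first)
    kv <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    primer_map <- structure(vapply(kv, `[`, character(1L), 2L),
                            names = vapply(kv, `[`, character(1L), 1L))
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  suppressWarnings(band_matrix(m, primer_map))
}

#' Write a band matrix to TSV
#'
#' @param m a `band_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly
#' @export
write_band_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(m$primer_of_band)) {
    writeLines(paste0("#primer\t",
                      paste(names(m$primer_of_band), m$primer_of_band,
                            sep = "=", collapse = ",")), con)
  }
  df <- data.frame(strain = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Jaccard distance between two binary band vectors
#'
#' `d = 1 - |a AND b| / |a OR b|`; double absence carries no information and
#' does not enter the denominator. Two all-zero vectors are assigned distance
#' 0 by convention (flagged with a message).
#'
#' @param a,b equal-length binary vectors.
#' @return distance in `[0, 1]`
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (!all(c(a, b) %in% c(0, 1))) stop("vectors must be binary")
  union <- sum(a | b)
  if (union == 0L) {
    message("both band vectors all-zero; Jaccard distance set to 0")
    return(0)
  }
  1 - sum(a & b) / union
}

# full pairwise Jaccard matrix via the binary metric of stats::dist;
# all-zero pairs (NaN) mapped to the 0 convention
jaccard_dist_matrix <- function(values) {
  d <- stats::dist(values, method = "binary")
  d[is.nan(d)] <- 0
  d
}

#' Cluster strains from an ISSR band matrix
#'
#' Pairwise Jaccard distances followed by agglomerative clustering.
#'
#' @param m a `band_matrix` with at least two strains.
#' @param linkage agglomeration method (default `"average"`).
#' @return list with `hclust`, `phylo`, `order` (leaf labels) and `dist`
#' @export
issr_tree <- function(m, linkage = "average") {
  stopifnot(inherits(m, "band_matrix"))
  if (nrow(m$values) < 2L) stop("need >= 2 strains to cluster")
  d <- jaccard_dist_matrix(m$values)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, phylo = ape::as.phylo(hc),
       order = hc$labels[hc$order], dist = d)
}

#' Polymorphic-band counts per primer
#'
#' @param m a `band_matrix`.
#' @param primer_of_band named character vector band id -> primer; defaults
#'   to the mapping stored in `m`.
#' @return list with `per_primer` (data.frame `primer`, `n_bands`), `total`
#'   and `mean_per_primer` (= total / number of primers)
#' @export
band_summary <- function(m, primer_of_band = m$primer_of_band) {
  if (is.null(primer_of_band)) stop("no band-to-primer mapping available")
  bands <- colnames(m$values)
  unmapped <- setdiff(bands, names(primer_of_band))
  if (length(unmapped) > 0L) {
    stop("bands with no primer mapping: ", paste(unmapped, collapse = ", "))
  }
  primers <- sort(unique(unname(primer_of_band)))
  counts <- vapply(primers, function(p) {
    sum(primer_of_band[bands] == p)
  }, integer(1L))
  total <- length(bands)
  list(per_primer = data.frame(primer = primers, n_bands = counts,
                               row.names = NULL, stringsAsFactors = FALSE),
       total = total,
       mean_per_primer = total / length(primers))
}
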