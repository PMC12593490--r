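#' Construct a per-strain haplotype count table
#'
#' Holds, for one strain, the number of reads supporting each window haplotype
#' at each MNP marker. A window haplotype is the string of bases observed at
#' the marker's SNP positions on a single sequencing fragment; only fragments
#' spanning all window SNPs contribute (the count-extraction adapter contract).
#'
#' @param strain strain identifier.
#' @param entries named list, one element per marker id, each a named integer
#'   vector of read counts keyed by haplotype string (A/C/G/T alphabet).
#' @return an object of class `count_table`
#' @export
count_table <- function(strain, entries) {
  stopifnot(is.character(strain), length(strain) == 1L, is.list(entries))
  for (m in names(entries)) {
    cnt <- entries[[m]]
    if (length(cnt) > 0L) {
      if (is.null(names(cnt)) || any(names(cnt) == "")) {
        stop("unnamed haplotype count at marker ", m)
      }
      if (any(cnt < 0)) stop("negative read count at marker ", m)
      if (length(unique(nchar(names(cnt)))) > 1L) {
        stop("inconsistent haplotype length within marker ", m)
      }
      entries[[m]] <- structure(as.integer(cnt), names = names(cnt))
    }
  }
  structure(list(strain = strain, entries = entries), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  tot <- sum(vapply(x$entries, sum, numeric(1L)))
  cat(sprintf("count_table: strain %s, %d markers, %d reads total\n",
              x$strain, length(x$entries), tot))
  invisible(x)
}

#' Read haplotype count tables from TSV
#'
#' Expects columns `strain`, `marker_id`, `haplotype`, `count`. Rows are
#' grouped by marker; duplicate (marker, haplotype) rows are summed.
#'
#' @param path TSV file.
#' @return named list of `count_table` objects, one per strain present.
#' @export
read_count_tables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "integer"))
  needed <- c("strain", "marker_id", "haplotype", "count")
  if (!all(needed %in% names(df))) {
    stop("count table must have columns: ", paste(needed, collapse = ", "))
  }
  out <- lapply(split(df, df$strain), function(d) {
    entries <- lapply(split(d, d$marker_id), function(e) {
      tapply(e$count, e$haplotype, sum)
    })
    entries <- lapply(entries, function(v) structure(as.integer(v), names = names(v)))
    count_table(d$strain[1L], entries)
  })
  out[order(names(out))]
}

#' Read a single-strain haplotype count table
#'
#' @param path TSV file (see [read_count_tables()]).
#' @param strain optional strain to select when the file holds several.
#' @return a `count_table`
#' @export
read_count_table <- function(path, strain = NULL) {
  tabs <- read_count_tables(path)
  if (is.null(strain)) {
    if (length(tabs) != 1L) {
      stop("file contains ", length(tabs),
           " strains; pass `strain` to select one of: ",
           paste(names(tabs), collapse = ", "))
    }
    return(tabs[[1L]])
  }
  if (!strain %in% names(tabs)) stop("strain not in file: ", strain)
  tabs[[strain]]
}

#' Write haplotype count tables to TSV
#'
#' @param counts a `count_table` or a list of them.
#' @param path output TSV.
#' @return `path`, invisibly
#' @export
write_count_tables <- function(counts, path) {
  if (inherits(counts, "count_table")) counts <- list(counts)
  rows <- lapply(counts, function(ct) {
    marker_rows <- lapply(names(ct$entries), function(m) {
      cnt <- ct$entries[[m]]
      if (length(cnt) == 0L) return(NULL)
      data.frame(strain = ct$strain, marker_id = m,
                 haplotype = names(cnt), count = as.integer(cnt),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, marker_rows)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
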