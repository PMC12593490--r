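MNPDB_SCHEMA <- "mnpkit-db"
MNPDB_VERSION <- 1L

#' Save a marker database to a portable container
#'
#' The database is written as a schema-tagged, versioned JSON document
#' readable on any platform, so a genotype library built once can be shared
#' and extended across installations. `load_database(save_database(db))`
#' reproduces `db` field-for-field.
#'
#' @param db an `mnp_db`
#' @param path output file (conventionally `.mnpdb.json`)
#' @return `path`, invisibly
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "mnp_db"))
  doc <- list(
    schema = MNPDB_SCHEMA,
    version = MNPDB_VERSION,
    meta = db$meta,
    markers = marker_rows_to_list(db$markers),
    profiles = unname(lapply(db$profiles, profile_to_list))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

marker_rows_to_list <- function(markers) {
  lapply(seq_len(nrow(markers)), function(i) {
    row <- list(
      marker_id = markers$marker_id[i],
      chrom = markers$chrom[i],
      start = markers$start[i],
      end = markers$end[i],
      n_snps = markers$n_snps[i],
      snp_positions = as.integer(markers$snp_positions[[i]]),
      pic = markers$pic[i]
    )
    if (!is.null(markers$words)) {
      w <- markers$words[[i]]
      row$words <- as.list(w)
    }
    row
  })
}

profile_to_list <- function(p) {
  list(
    strain = p$strain,
    calls = lapply(names(p$calls), function(m) {
      g <- p$calls[[m]]
      list(marker_id = m,
           haplotypes = if (g$missing) NULL else as.list(g$haplotypes),
           support = as.list(g$support),
           total_reads = g$total_reads)
    })
  )
}

#' Load a marker database saved by [save_database()]
#'
#' @param path file written by [save_database()].
#' @return an `mnp_db`
#' @export
load_database <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot read database '", path, "': ",
                             conditionMessage(e))
  )
  if (!identical(doc$schema, MNPDB_SCHEMA)) {
    stop("not a mnpkit database: schema tag is ",
         if (is.null(doc$schema)) "absent" else doc$schema)
  }
  if (!identical(as.integer(doc$version), MNPDB_VERSION)) {
    stop("database schema version ", doc$version,
         " is not supported by this build (expected ", MNPDB_VERSION, ")")
  }
  markers <- marker_list_to_rows(doc$markers)
  profiles <- lapply(doc$profiles, function(pl) {
    calls <- lapply(pl$calls, function(cl) {
      missing <- is.null(cl$haplotypes)
      support <- structure(as.integer(unlist(cl$support, use.names = FALSE)),
                           names = names(cl$support))
      if (length(support) == 0L) support <- structure(integer(0), names = character(0))
      structure(list(
        haplotypes = if (missing) NULL else sort(unlist(cl$haplotypes)),
        support = support,
        total_reads = as.integer(cl$total_reads),
        missing = missing
      ), class = "mnp_genotype")
    })
    names(calls) <- vapply(pl$calls, `[[`, character(1L), "marker_id")
    mnp_profile(pl$strain, calls)
  })
  meta <- doc$meta
  if (is.null(meta)) meta <- list()
  build_database(markers, profiles, meta)
}

marker_list_to_rows <- function(ml) {
  df <- data.frame(
    marker_id = vapply(ml, `[[`, character(1L), "marker_id"),
    chrom = vapply(ml, `[[`, character(1L), "chrom"),
    start = vapply(ml, function(m) as.integer(m$start), integer(1L)),
    end = vapply(ml, function(m) as.integer(m$end), integer(1L)),
    n_snps = vapply(ml, function(m) as.integer(m$n_snps), integer(1L)),
    pic = vapply(ml, function(m) as.numeric(m$pic), numeric(1L)),
    stringsAsFactors = FALSE
  )
  df$snp_positions <- lapply(ml, function(m)
    as.integer(unlist(m$snp_positions, use.names = FALSE)))
  if (length(ml) > 0L && !is.null(ml[[1L]]$words)) {
    df$words <- lapply(ml, function(m)
      structure(as.numeric(unlist(m$words, use.names = FALSE)),
                names = names(m$words)))
  }
  df[, c("marker_id", "chrom", "start", "end", "n_snps", "snp_positions",
         "pic", intersect("words", names(df)))]
}

#' Write a labelled square matrix to TSV
#'
#' @param m numeric matrix with identical row and column (strain) labels.
#' @param path output TSV; first column holds the row labels.
#' @return `path`, invisibly
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) > 0L, !is.null(rownames(m)))
  df <- data.frame(strain = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square matrix written by [write_matrix()]
#'
#' @param path TSV file.
#' @return numeric matrix with dimnames
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] object or an `hclust`.
#' @param path output file.
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
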