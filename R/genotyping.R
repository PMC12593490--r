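#' Call an MNP genotype from haplotype read counts
#'
#' A marker's call is the set of window haplotypes whose read fraction reaches
#' the heterozygote threshold. With fewer than `min_reads` total reads the
#' marker is MISSING. When more than two haplotypes pass (contamination or
#' sequencing error in a dikaryon, which carries at most two), the two with
#' the highest counts are kept, ties broken lexicographically by haplotype
#' string, and the event is signalled as a condition of class
#' `mnpkit_excess_haplotypes`.
#'
#' @param counts named integer vector of reads per haplotype string.
#' @param het_threshold minimum read fraction for a haplotype to be retained
#'   (inclusive: a fraction exactly at the threshold is kept).
#' @param min_reads minimum total reads for a call.
#' @return list of class `mnp_genotype`: `haplotypes` (character, sorted;
#'   `NULL` when MISSING), `support` (named integer), `total_reads`,
#'   `missing` (logical)
#' @export
call_genotype <- function(counts, het_threshold = 0.1, min_reads = 10L) {
  if (length(counts) == 0L) {
    return(structure(list(haplotypes = NULL,
                          support = structure(integer(0), names = character(0)),
                          total_reads = 0L, missing = TRUE),
                     class = "mnp_genotype"))
  }
  if (any(counts < 0)) stop("negative read count")
  total <- sum(counts)
  if (total < min_reads) {
    return(structure(list(haplotypes = NULL, support = structure(
      as.integer(counts), names = names(counts)),
      total_reads = as.integer(total), missing = TRUE),
      class = "mnp_genotype"))
  }
  frac <- counts / total
  pass <- names(counts)[frac >= het_threshold]
  if (length(pass) == 0L) {
    return(structure(list(haplotypes = NULL, support = structure(
      as.integer(counts), names = names(counts)),
      total_reads = as.integer(total), missing = TRUE),
      class = "mnp_genotype"))
  }
  if (length(pass) > 2L) {
    ord <- order(-counts[pass], pass)
    dropped <- pass[ord][-(1:2)]
    pass <- pass[ord][1:2]
    signalCondition(structure(
      class = c("mnpkit_excess_haplotypes", "condition"),
      list(message = paste0(">2 haplotypes passed threshold; dropped: ",
                            paste(dropped, collapse = ",")),
           call = NULL)))
  }
  structure(list(haplotypes = sort(pass),
                 support = structure(as.integer(counts[sort(pass)]),
                                     names = sort(pass)),
                 total_reads = as.integer(total), missing = FALSE),
            class = "mnp_genotype")
}

#' @export
print.mnp_genotype <- function(x, ...) {
  if (x$missing) {
    cat(sprintf("mnp_genotype: MISSING (%d reads)\n", x$total_reads))
  } else {
    cat(sprintf("mnp_genotype: %s (%d reads)\n",
                paste(x$haplotypes, collapse = "/"), x$total_reads))
  }
  invisible(x)
}

# canonical comparable genotype string: "hap" or "hapA/hapB" (sorted), NA if
# missing
genotype_key <- function(g) {
  if (g$missing) NA_character_ else paste(g$haplotypes, collapse = "/")
}

#' Genotype one strain at a set of markers
#'
#' Every marker in `markers` receives a call; markers with no counts are
#' MISSING. Counts referencing a marker id not in `markers` raise a warning
#' and are ignored (`strict = TRUE` turns this into an error).
#'
#' @param counts a `count_table` for the strain.
#' @param markers marker data.frame (needs a `marker_id` column).
#' @param het_threshold,min_reads passed to [call_genotype()].
#' @param strict error instead of warn on unknown marker ids.
#' @return an `mnp_profile`: list with `strain`, `calls` (named list of
#'   `mnp_genotype`), and `geno` (named character vector of canonical
#'   genotype strings, `NA` = MISSING)
#' @export
genotype_strain <- function(counts, markers, het_threshold = 0.1,
                            min_reads = 10L, strict = FALSE) {
  ids <- markers$marker_id
  unknown <- setdiff(names(counts$entries), ids)
  if (length(unknown) > 0L) {
    msg <- paste0("counts reference unknown marker ids: ",
                  paste(utils::head(unknown, 5L), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  calls <- lapply(ids, function(m) {
    cnt <- counts$entries[[m]]
    if (is.null(cnt)) cnt <- integer(0)
    call_genotype(cnt, het_threshold, min_reads)
  })
  names(calls) <- ids
  mnp_profile(counts$strain, calls)
}

#' Construct an MNP genotype profile
#'
#' @param strain strain identifier.
#' @param calls named list of `mnp_genotype`, keyed by marker id.
#' @return an object of class `mnp_profile`
#' @export
mnp_profile <- function(strain, calls) {
  geno <- vapply(calls, genotype_key, character(1L))
  structure(list(strain = strain, calls = calls, geno = geno),
            class = "mnp_profile")
}

#' @export
print.mnp_profile <- function(x, ...) {
  n_missing <- sum(is.na(x$geno))
  cat(sprintf("mnp_profile: strain %s, %d markers (%d missing, %d het)\n",
              x$strain, length(x$geno), n_missing,
              sum(grepl("/", x$geno, fixed = TRUE), na.rm = TRUE)))
  invisible(x)
}

#' Assemble a marker database
#'
#' @param markers marker data.frame from [select_markers()].
#' @param profiles list of `mnp_profile`; each must cover exactly the marker
#'   ids in `markers`; strain ids must be unique.
#' @param meta named list of free-form metadata (reference name, creation
#'   parameters, tool version, ...).
#' @return an object of class `mnp_db`
#' @export
build_database <- function(markers, profiles = list(), meta = list()) {
  strains <- vapply(profiles, `[[`, character(1L), "strain")
  if (anyDuplicated(strains)) {
    stop("duplicate strain id: ", strains[duplicated(strains)][1L])
  }
  names(profiles) <- strains
  db <- structure(list(markers = markers, profiles = profiles, meta = meta),
                  class = "mnp_db")
  for (p in profiles) check_profile_universe(db, p)
  db
}

check_profile_universe <- function(db, profile) {
  if (!identical(sort(names(profile$calls)), sort(db$markers$marker_id))) {
    stop("profile for strain ", profile$strain,
         " does not key exactly the database markers")
  }
  invisible(TRUE)
}

#' Add a strain profile to a database
#'
#' Incremental: existing entries are untouched, so a new variety can be
#' genotyped against an established marker library without re-building it.
#'
#' @param db an `mnp_db`
#' @param profile an `mnp_profile` for a strain not yet in `db`
#' @return the extended `mnp_db`
#' @export
db_add_strain <- function(db, profile) {
  if (profile$strain %in% names(db$profiles)) {
    stop("duplicate strain id: ", profile$strain)
  }
  check_profile_universe(db, profile)
  db$profiles[[profile$strain]] <- profile
  db
}

#' @export
print.mnp_db <- function(x, ...) {
  cat(sprintf("mnp_db: %d markers x %d strains\n",
              nrow(x$markers), length(x$profiles)))
  if (length(x$meta) > 0L) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
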