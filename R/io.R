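# Tab-separated readers/writers for the pipeline's exchange formats.
# Everything is plain text so runs are diffable and portable.

#' Read / write an expression matrix as TSV
#'
#' Layout: one header row, first column `feature_id`, remaining columns one
#' per subject; rows are features.
#'
#' @param expr an `expr_matrix`.
#' @param path file path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an `expr_matrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(feature_id = rownames(expr), unclass(expr),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param transform declared transform state of the stored values.
#' @export
read_expression_tsv <- function(path, transform = "normalized") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, transform = transform)
}

#' Read / write a clinical cohort as TSV
#'
#' Columns: `subject_id`, `days_to_death`, `event` (0/1), `stage`.
#'
#' @param cohort a `clinical_cohort`.
#' @param path file path.
#' @export
write_clinical_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  df <- as.data.frame(cohort)
  df$event <- as.integer(df$event)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  clinical_cohort(
    subject_id = df$subject_id,
    days_to_death = df$days_to_death,
    event = as.logical(df$event),
    stage = df$stage
  )
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line — set name, description, then
#' tab-separated member gene IDs. An empty collection writes an empty file.
#'
#' @param collection a [gene_set_collection()].
#' @param path file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param universe gene universe for the collection; defaults to the union
#'   of all member genes in the file.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, descriptions)
}

#' Write a screen-record table as TSV
#' @param records a [screen_all()] table.
#' @param path file path.
#' @export
write_screen_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enrichment/triage table as TSV
#'
#' The `member_hits` list column is comma-joined; every other column is
#' written as is.
#'
#' @param functions an enrichment table.
#' @param path file path.
#' @export
write_enrichment_tsv <- function(functions, path) {
  df <- functions
  if (!is.null(df$member_hits)) {
    df$member_hits <- vapply(df$member_hits, paste, character(1), collapse = ",")
  }
  attr(df, "cluster_tree") <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a calibration report
#'
#' Emits a JSON summary (iterations, quantiles, false-positive rates,
#' normality p, seed) alongside a TSV of the pooled null HRz samples.
#'
#' @param calibration a [calibrate()] result.
#' @param json_path,hrz_path output paths; either may be `NULL` to skip.
#' @export
write_calibration_report <- function(calibration, json_path, hrz_path = NULL) {
  stopifnot(inherits(calibration, "null_calibration"))
  if (!is.null(json_path)) {
    summary <- calibration[setdiff(names(calibration), "hrz_samples")]
    jsonlite::write_json(summary, json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(hrz_path)) {
    utils::write.table(
      data.frame(hr_z = calibration$hrz_samples), hrz_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(json_path)
}
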