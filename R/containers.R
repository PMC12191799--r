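#' Construct an expression matrix container
#'
#' A thin wrapper around a numeric features x subjects matrix that tracks its
#' transform state: `"normalized"` (library/GC-normalized abundance, as
#' delivered upstream) or `"log2p4"` (after [log2p4_transform()]). Rows are
#' features, columns subjects; both must carry unique names.
#'
#' @param values numeric matrix, features in rows, subjects in columns,
#'   with unique `rownames` (feature IDs) and `colnames` (subject IDs).
#' @param transform `"normalized"` or `"log2p4"`.
#' @return an `expr_matrix`: the matrix with a `transform_state` attribute.
#' @export
expression_matrix <- function(values, transform = c("normalized", "log2p4")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have positive dimensions", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("rows must carry unique feature IDs", call. = FALSE)
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("columns must carry unique subject IDs", call. = FALSE)
  }
  if (transform == "normalized" && any(values < 0, na.rm = TRUE)) {
    stop("normalized expression values must be non-negative", call. = FALSE)
  }
  if (transform == "log2p4" && any(values < 2, na.rm = TRUE)) {
    stop("log2(x+4) values cannot fall below 2.0", call. = FALSE)
  }
  structure(values, transform_state = transform, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features x %d subjects [%s]\n",
    nrow(x), ncol(x), transform_state(x)
  ))
  invisible(x)
}

#' Transform state of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"normalized"` or `"log2p4"`.
#' @export
transform_state <- function(x) attr(x, "transform_state")

# subsetting keeps the class and transform state when the result is still
# a matrix; standard drop semantics otherwise
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    out <- structure(out,
      transform_state = transform_state(x),
      class = class(x)
    )
  }
  out
}

#' Construct a clinical cohort table
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param days_to_death positive integer days from diagnosis to death (or to
#'   censoring when `event` is `FALSE`).
#' @param event logical; `TRUE` for an observed death. Defaults to all
#'   events, matching a cohort assembled on observed `days_to_death`.
#' @param stage tumor stage label per subject (recycled if length 1).
#' @return a `data.frame` with class `clinical_cohort` and columns
#'   `subject_id`, `days_to_death`, `event`, `stage`.
#' @export
clinical_cohort <- function(subject_id, days_to_death,
                            event = TRUE, stage = "IIIC") {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("subject IDs must be unique", call. = FALSE)
  n <- length(subject_id)
  days <- as.integer(days_to_death)
  if (length(days) != n) stop("days_to_death length mismatch", call. = FALSE)
  if (any(days <= 0L, na.rm = TRUE)) {
    stop("days_to_death must be positive integers", call. = FALSE)
  }
  out <- data.frame(
    subject_id = subject_id,
    days_to_death = days,
    event = rep_len(as.logical(event), n),
    stage = rep_len(as.character(stage), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clinical_cohort", "data.frame")
  out
}

#' Gene-set collection
#'
#' Holds named gene sets (as read from or written to GMT) together with the
#' gene universe they are tested against. Members outside the universe are
#' dropped at construction (harmonization).
#'
#' @param sets named list of character vectors; names are set IDs.
#' @param universe character vector of all candidate gene IDs.
#' @param descriptions optional character vector parallel to `sets`.
#' @return a `gene_set_collection` list with elements `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (is.null(names(sets)) && length(sets) > 0L) {
    stop("gene sets must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("set IDs must be unique", call. = FALSE)
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(g) intersect(as.character(g), universe))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(
    list(sets = sets, descriptions = descriptions, universe = universe),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d sets over a universe of %d genes\n",
    length(x$sets), length(x$universe)
  ))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
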