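#' Apply the cohort inclusion filters
#'
#' Retains subjects matching the stage label whose `days_to_death` lies
#' strictly between `min_days` and `max_days`. The defaults reproduce the
#' stage-IIIC, 0 < days < 3650 (10-year) inclusion rule used to assemble the
#' ovarian-cancer study cohort. Subject order is preserved and the filter is
#' idempotent.
#'
#' @param cohort a [clinical_cohort()].
#' @param stage_filter stage label to retain, or `NULL` to skip the stage
#'   criterion.
#' @param min_days,max_days exclusive bounds on `days_to_death`.
#' @param require_event if `TRUE` (default) only subjects with an observed
#'   death are retained, mirroring an inclusion criterion of integer
#'   days-to-death; censored subjects are dropped.
#' @return the filtered `clinical_cohort`; empty results raise a warning,
#'   not an error.
#' @export
filter_cohort <- function(cohort, stage_filter = "IIIC",
                          min_days = 0L, max_days = 3650L,
                          require_event = TRUE) {
  stopifnot(inherits(cohort, "clinical_cohort"), nrow(cohort) > 0L)
  keep <- cohort$days_to_death > min_days & cohort$days_to_death < max_days
  if (!is.null(stage_filter)) keep <- keep & cohort$stage == stage_filter
  if (require_event) keep <- keep & cohort$event
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("cohort filter retained no subjects", call. = FALSE)
  out
}

#' Drop subjects with extreme anchor-gene expression
#'
#' Computes per-subject Z-scores of the anchor gene's normalized expression
#' and removes subjects with `|Z| >= z_threshold`. This reproduces the
#' removal of a single cohort individual whose anchor transcript count sat
#' 16.2 standard deviations above the mean. If the anchor has zero variance
#' across subjects the Z-score is undefined and nothing is removed.
#'
#' @param expr an [expression_matrix()] in the `normalized` state.
#' @param anchor anchor feature ID; must be present.
#' @param z_threshold absolute Z-score at or beyond which a subject is
#'   dropped. Default 6 — far beyond ordinary biological variation but well
#'   inside the 16.2-sd case it is meant to catch.
#' @return the filtered `expr_matrix`, with an `outliers_removed` attribute:
#'   a data.frame of dropped subjects and their anchor Z-scores.
#' @export
remove_anchor_outliers <- function(expr, anchor, z_threshold = 6) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (transform_state(expr) != "normalized") {
    stop("outlier screening runs on normalized (pre-log) values", call. = FALSE)
  }
  if (!anchor %in% rownames(expr)) {
    stop(sprintf("anchor feature '%s' not found", anchor), call. = FALSE)
  }
  v <- expr[anchor, ]
  s <- stats::sd(v)
  if (is.na(s) || s == 0) {
    report <- data.frame(subject_id = character(), z = numeric())
  } else {
    z <- (v - mean(v)) / s
    drop <- abs(z) >= z_threshold
    report <- data.frame(
      subject_id = colnames(expr)[drop], z = unname(z[drop]),
      stringsAsFactors = FALSE
    )
  }
  keep <- setdiff(colnames(expr), report$subject_id)
  out <- expr[, keep, drop = FALSE]
  attr(out, "outliers_removed") <- report
  out
}

#' log2(x + 4) scaling
#'
#' Replaces every normalized value v by `log2(v + 4)`. The +4 offset gives a
#' minimum working value of 2.0 when counts are near zero, which bounds the
#' denominator of every downstream anchor/gene ratio away from zero and
#' scales the ratios more uniformly.
#'
#' @param expr an [expression_matrix()] in the `normalized` state.
#' @return the transformed `expr_matrix` with `transform_state = "log2p4"`.
#' @export
log2p4_transform <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (transform_state(expr) != "normalized") {
    stop("input is already transformed", call. = FALSE)
  }
  if (any(expr < 0)) stop("negative expression value", call. = FALSE)
  expression_matrix(log2(unclass(expr) + 4), transform = "log2p4")
}

#' Anchor/gene expression ratios
#'
#' For every feature i and subject s computes
#' `expr[anchor, s] / expr[i, s]` on the log2(x+4) scale. Because the
#' transform bounds every value at 2.0, the denominator is never close to
#' zero and all ratios are positive. The anchor's own row (identically 1) is
#' excluded.
#'
#' @param expr an [expression_matrix()] in the `log2p4` state.
#' @param anchor anchor feature ID (the ratio numerator).
#' @return a `ratio_matrix`: positive matrix, one row per non-anchor
#'   feature, with an `anchor` attribute.
#' @export
compute_ratios <- function(expr, anchor) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (transform_state(expr) != "log2p4") {
    stop("ratios are computed on log2(x+4) values; run log2p4_transform() first",
      call. = FALSE
    )
  }
  if (!anchor %in% rownames(expr)) {
    stop(sprintf("anchor feature '%s' not found", anchor), call. = FALSE)
  }
  num <- expr[anchor, ]
  m <- unclass(expr)[setdiff(rownames(expr), anchor), , drop = FALSE]
  ratios <- sweep(1 / m, 2, num, `*`)
  structure(ratios, anchor = anchor, class = c("ratio_matrix", "matrix", "array"))
}

# keep class and anchor through subsetting while the result is a matrix
#' @export
`[.ratio_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    out <- structure(out, anchor = attr(x, "anchor"), class = class(x))
  }
  out
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf(
    "<ratio_matrix> anchor %s over %d features x %d subjects\n",
    attr(x, "anchor"), nrow(x), ncol(x)
  ))
  invisible(x)
}

#' Align expression and clinical tables on their common subjects
#'
#' Subjects present in only one of the two inputs are dropped with a
#' warning; the survivors are ordered identically in both outputs.
#'
#' @param expr an `expr_matrix` (or `ratio_matrix`).
#' @param cohort a `clinical_cohort`.
#' @return list with elements `expr` and `cohort` on the common subject set.
#' @export
align_subjects <- function(expr, cohort) {
  common <- intersect(colnames(expr), cohort$subject_id)
  if (length(common) == 0L) stop("no subjects in common", call. = FALSE)
  n_drop <- (ncol(expr) - length(common)) + (nrow(cohort) - length(common))
  if (n_drop > 0L) {
    warning(sprintf(
      "%d subject record(s) present in only one input were dropped", n_drop
    ), call. = FALSE)
  }
  cohort_out <- cohort[match(common, cohort$subject_id), , drop = FALSE]
  rownames(cohort_out) <- NULL
  list(expr = expr[, common, drop = FALSE], cohort = cohort_out)
}

#' Median-of-ratios library-size normalizer (plumbing)
#'
#' Optional convenience for raw count input; the screening pipeline
#' otherwise accepts upstream normalization as given. Size factors follow
#' the median-of-ratios construction over features with nonzero geometric
#' mean.
#'
#' @param expr an `expr_matrix` of raw, non-negative counts
#'   (`transform_state = "normalized"` is reused for the output).
#' @return the normalized `expr_matrix`.
#' @keywords internal
#' @export
normalize_library_size <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- unclass(expr)
  logm <- log(m)
  ok <- is.finite(rowMeans(logm))
  if (!any(ok)) stop("no feature has all-positive counts", call. = FALSE)
  ref <- rowMeans(logm[ok, , drop = FALSE])
  sf <- apply(logm[ok, , drop = FALSE], 2, function(col) exp(stats::median(col - ref)))
  expression_matrix(sweep(m, 2, sf, `/`), transform = "normalized")
}
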