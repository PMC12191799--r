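#' Split a cohort at the median of a per-subject value
#'
#' The low group takes values less than or equal to the sample median (ties
#' at the median go low), the high group values strictly above. With an odd
#' number of distinct values the low group is therefore the larger one.
#'
#' @param values named numeric vector, one value per subject; names are
#'   subject IDs. At least 4 subjects, not all values identical.
#' @return a `stratified_groups` list: `low_ids`, `high_ids`,
#'   `median_value`.
#' @export
median_stratify <- function(values) {
  if (is.null(names(values))) stop("`values` must be named by subject", call. = FALSE)
  if (length(values) < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (length(unique(values)) < 2L) {
    stop("degenerate: all values identical", call. = FALSE)
  }
  med <- stats::median(values)
  high <- values > med
  structure(
    list(
      low_ids = names(values)[!high],
      high_ids = names(values)[high],
      median_value = med
    ),
    class = "stratified_groups"
  )
}

# Surv response + high-group indicator for a stratification, in cohort order.
.group_indicator <- function(groups, cohort) {
  ids <- cohort$subject_id
  if (!setequal(c(groups$low_ids, groups$high_ids), ids)) {
    stop("stratified groups do not partition the cohort", call. = FALSE)
  }
  ids %in% groups$high_ids
}

#' Kaplan-Meier log-rank p-value for a two-group stratification
#'
#' Two-sided log-rank test comparing the survival curves of the low and
#' high groups, via [survival::survdiff()].
#'
#' @param groups a [median_stratify()] result.
#' @param cohort a `clinical_cohort` covering exactly the stratified
#'   subjects.
#' @return the chi-square tail p-value (1 df), or `NA` if the test is
#'   undefined (a group is empty or there are no events).
#' @export
km_logrank <- function(groups, cohort) {
  high <- .group_indicator(groups, cohort)
  .logrank_p(high, cohort$days_to_death, cohort$event)
}

.logrank_p <- function(high, time, event) {
  if (!any(high) || all(high) || !any(event)) return(NA_real_)
  tryCatch(
    {
      sd <- survival::survdiff(
        survival::Surv(time, event) ~ high
      )
      unname(1 - stats::pchisq(sd$chisq, df = 1))
    },
    error = function(e) NA_real_
  )
}

#' Univariate Cox hazard ratio of the high group versus the low group
#'
#' Fits a proportional-hazards model with the single binary covariate
#' `indicator(high group)` and returns the exponentiated coefficient — the
#' risk ratio of the high group relative to the low group. Ties are handled
#' with the Efron approximation (fixed, for reproducibility).
#'
#' @inheritParams km_logrank
#' @return the hazard ratio (positive numeric scalar), with attributes
#'   `wald_p` (Wald test p-value) and `se_log_hr`; `NA` on a degenerate or
#'   non-convergent fit.
#' @export
cox_hr <- function(groups, cohort) {
  high <- .group_indicator(groups, cohort)
  fit <- .cox_fit(high, cohort$days_to_death, cohort$event)
  structure(fit$hr, wald_p = fit$wald_p, se_log_hr = fit$se)
}

# Fast single-covariate Cox fit via survival::coxph.fit (Efron ties).
# Returns list(hr, se, wald_p); NAs when the fit is degenerate, separated
# (|log HR| > 15) or otherwise unusable.
.cox_fit <- function(high, time, event) {
  bad <- list(hr = NA_real_, se = NA_real_, wald_p = NA_real_,
              reason = "degenerate")
  if (!any(high) || all(high) || !any(event)) return(bad)
  y <- survival::Surv(time, event)
  fit <- tryCatch(
    survival::coxph.fit(
      x = matrix(as.double(high), ncol = 1L), y = y,
      strata = NULL, offset = NULL, init = 0,
      control = survival::coxph.control(),
      weights = NULL, method = "efron", rownames = NULL
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || is.na(fit$coefficients[1L])) return(bad)
  b <- unname(fit$coefficients[1L])
  v <- fit$var[1L, 1L]
  if (!is.finite(b) || abs(b) > 15 || !is.finite(v) || v <= 0) {
    bad$reason <- "nonconvergence"
    return(bad)
  }
  se <- sqrt(v)
  list(
    hr = exp(b), se = se,
    wald_p = 2 * stats::pnorm(-abs(b / se)),
    reason = NA_character_
  )
}

#' Significance-improvement filter
#'
#' A ratio stratification is retained only when its KM log-rank p-value is
#' at least 10% more significant than that of the corresponding single-gene
#' stratification, read multiplicatively on the p-value scale:
#' `p_ratio <= factor * p_single` with `factor = 0.9`.
#'
#' @param p_ratio,p_single log-rank p-values of the ratio and single-gene
#'   median stratifications (vectorized).
#' @param factor multiplicative improvement factor; 0.9 encodes "10% more
#'   significant".
#' @return logical vector; `NA` where either p-value is missing.
#' @examples
#' improvement_filter(0.009, 0.01)   # TRUE
#' improvement_filter(0.0095, 0.01)  # FALSE
#' @export
improvement_filter <- function(p_ratio, p_single, factor = 0.9) {
  p_ratio <= factor * p_single
}

#' Screen every feature's anchor ratio against survival
#'
#' For each non-anchor feature the cohort is median-stratified twice: by the
#' anchor/gene ratio and (as the baseline) by the single gene's own
#' expression. Each stratification gets a KM log-rank p-value; the ratio
#' stratification additionally gets a univariate Cox hazard ratio
#' (high vs low), which is symmetrized ([hr_sym()]) and Z-standardized
#' ([z_standardize()]) across all non-skipped features of the screen into
#' HRz. Degenerate or non-convergent features are skipped with a reason,
#' never aborting the screen.
#'
#' @param ratios a [compute_ratios()] result.
#' @param expr the log2(x+4) `expr_matrix` the ratios came from (used for
#'   the single-gene baseline stratification). Ignored when
#'   `compute_baseline = FALSE`.
#' @param cohort a `clinical_cohort`; its subjects must equal the ratio
#'   matrix columns.
#' @param improvement_factor see [improvement_filter()].
#' @param compute_baseline,compute_km switch off the single-gene baseline
#'   and/or the KM tests (the Monte Carlo null calibration needs only the
#'   Cox HRs, see [calibrate()]).
#' @return a `data.frame`, one row per feature ordered by feature ID, with
#'   columns `feature_id`, `cox_hr`, `cox_wald_p`, `km_p_single`,
#'   `km_p_ratio`, `hr_sym`, `hr_z`, `passes_improvement`, `group`
#'   (initially `"ns"`; see [classify_groups()]), `skipped_reason`.
#' @export
screen_all <- function(ratios, expr = NULL, cohort,
                       improvement_factor = 0.9,
                       compute_baseline = TRUE, compute_km = TRUE) {
  stopifnot(inherits(ratios, "ratio_matrix"), inherits(cohort, "clinical_cohort"))
  if (!setequal(colnames(ratios), cohort$subject_id)) {
    stop("ratio matrix and cohort cover different subjects", call. = FALSE)
  }
  if (compute_baseline && is.null(expr)) {
    stop("`expr` is required for the single-gene baseline", call. = FALSE)
  }
  # canonical subject order => results invariant to input subject order
  ord <- order(cohort$subject_id)
  cohort <- cohort[ord, , drop = FALSE]
  ratios <- ratios[, cohort$subject_id, drop = FALSE]
  if (compute_baseline) expr <- expr[, cohort$subject_id, drop = FALSE]

  features <- sort(rownames(ratios))
  time <- cohort$days_to_death
  event <- cohort$event
  n <- length(features)

  cox <- rep(NA_real_, n)
  wald <- rep(NA_real_, n)
  p_ratio <- rep(NA_real_, n)
  p_single <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    v <- ratios[features[i], ]
    if (length(unique(v)) < 2L) {
      reason[i] <- "degenerate"
      next
    }
    high <- v > stats::median(v)
    fit <- .cox_fit(high, time, event)
    if (is.na(fit$hr)) {
      reason[i] <- fit$reason
      next
    }
    cox[i] <- fit$hr
    wald[i] <- fit$wald_p
    if (compute_km) {
      p_ratio[i] <- .logrank_p(high, time, event)
      if (compute_baseline) {
        g <- expr[features[i], ]
        if (length(unique(g)) >= 2L) {
          p_single[i] <- .logrank_p(g > stats::median(g), time, event)
        }
      }
    }
  }

  hrs <- rep(NA_real_, n)
  hrs[!is.na(cox)] <- hr_sym(cox[!is.na(cox)])
  hrz <- rep(NA_real_, n)
  if (sum(!is.na(hrs)) >= 2L && stats::sd(hrs, na.rm = TRUE) > 0) {
    hrz <- z_standardize(hrs)$hr_z
  }

  data.frame(
    feature_id = features,
    cox_hr = cox,
    cox_wald_p = wald,
    km_p_single = p_single,
    km_p_ratio = p_ratio,
    hr_sym = hrs,
    hr_z = hrz,
    passes_improvement = improvement_filter(p_ratio, p_single, improvement_factor),
    group = rep("ns", n),
    skipped_reason = reason,
    stringsAsFactors = FALSE
  )
}
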