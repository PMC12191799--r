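#' Randomize expression and survival to break all real associations
#'
#' Independently permutes each feature row across subjects and permutes the
#' survival records (days-to-death together with the event flag) across
#' subjects. Marginal distributions are preserved exactly; every
#' feature-survival and feature-anchor dependence is destroyed, which is the
#' null the Monte Carlo calibration samples from.
#'
#' @param expr an `expr_matrix` (any transform state).
#' @param cohort the aligned `clinical_cohort`.
#' @param rng_seed integer seed; the same seed reproduces the same
#'   randomization bit for bit.
#' @return list with the randomized `expr` and `cohort`.
#' @export
randomize_inputs <- function(expr, cohort, rng_seed) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(cohort, "clinical_cohort"))
  ns <- ncol(expr)
  withr::with_seed(as.integer(rng_seed), {
    m <- unclass(expr)
    for (i in seq_len(nrow(m))) {
      m[i, ] <- m[i, sample.int(ns)]
    }
    perm <- sample.int(nrow(cohort))
    cohort$days_to_death <- cohort$days_to_death[perm]
    cohort$event <- cohort$event[perm]
    list(
      expr = expression_matrix(m, transform = transform_state(expr)),
      cohort = cohort
    )
  })
}

#' Monte Carlo calibration of the HRz null distribution
#'
#' Repeatedly randomizes the inputs ([randomize_inputs()]), reruns the full
#' anchor-ratio screen (log2(x+4) transform, ratio construction, median
#' stratification, Cox HR, symmetrization, Z-standardization within the
#' replicate) and pools the resulting HRz values. From the pooled null it
#' reports the empirical 0.025/0.975 quantiles (the two-tailed alpha = 0.05
#' boundaries), the false-positive rate at the fixed +/-`threshold`
#' boundaries — both pooled and averaged over iterations — and a
#' Shapiro-Wilk normality p-value.
#'
#' @param expr the preprocessed (outlier-filtered, still `normalized`)
#'   `expr_matrix` including the anchor row.
#' @param cohort the aligned, filtered `clinical_cohort`.
#' @param anchor anchor feature ID.
#' @param n_iterations number of randomized replicates (default 25).
#' @param rng_seed master seed; per-iteration seeds are derived from it.
#' @param threshold fixed HRz group boundary used for the false-positive
#'   rate (default 2.0).
#' @return a `null_calibration` list: `n_iterations`, `hrz_samples`
#'   (pooled), `q025`, `q975`, `fp_rate_at_2` (pooled fraction of
#'   `|HRz| > threshold`), `fp_rate_per_iteration`, `fp_rate_mean`
#'   (average of the per-iteration fractions), `normality_p`, `threshold`,
#'   `seed`.
#' @export
calibrate <- function(expr, cohort, anchor, n_iterations = 25L,
                      rng_seed = 1L, threshold = 2.0) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(cohort, "clinical_cohort"))
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (!setequal(colnames(expr), cohort$subject_id)) {
    stop("expression and cohort must be aligned before calibration", call. = FALSE)
  }
  iter_seeds <- withr::with_seed(
    as.integer(rng_seed),
    sample.int(2147483646L, n_iterations)
  )
  pooled <- vector("list", n_iterations)
  fp_iter <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    rnd <- randomize_inputs(expr, cohort, iter_seeds[it])
    lg <- log2p4_transform(rnd$expr)
    ratios <- compute_ratios(lg, anchor)
    rec <- screen_all(ratios,
      cohort = rnd$cohort,
      compute_baseline = FALSE, compute_km = FALSE
    )
    z <- rec$hr_z[!is.na(rec$hr_z)]
    pooled[[it]] <- z
    fp_iter[it] <- mean(abs(z) > threshold)
  }
  z_all <- unlist(pooled)
  q <- stats::quantile(z_all, c(0.025, 0.975), names = FALSE)
  # Shapiro-Wilk is capped at n = 5000; subsample deterministically
  z_sw <- if (length(z_all) > 5000L) {
    withr::with_seed(as.integer(rng_seed), sample(z_all, 5000L))
  } else {
    z_all
  }
  structure(
    list(
      n_iterations = as.integer(n_iterations),
      hrz_samples = z_all,
      q025 = q[1], q975 = q[2],
      fp_rate_at_2 = mean(abs(z_all) > threshold),
      fp_rate_per_iteration = fp_iter,
      fp_rate_mean = mean(fp_iter),
      normality_p = stats::shapiro.test(z_sw)$p.value,
      threshold = threshold,
      seed = as.integer(rng_seed)
    ),
    class = "null_calibration"
  )
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<null_calibration> %d iterations, %d pooled null HRz values\n",
      "  empirical quantiles: q025 = %.3f, q975 = %.3f\n",
      "  FP rate at |HRz| > %.1f: pooled %.4f, per-iteration mean %.4f\n",
      "  Shapiro-Wilk normality p = %.3g\n"
    ),
    x$n_iterations, length(x$hrz_samples), x$q025, x$q975,
    x$threshold, x$fp_rate_at_2, x$fp_rate_mean, x$normality_p
  ))
  invisible(x)
}

#' HRz group boundaries
#'
#' Either the fixed +/-2.0 boundaries that define the anchor-dependent
#' (`OPCML_plus`) and anchor-independent (`GENEi_plus`) tails, or the
#' empirical quantiles of a Monte Carlo [calibrate()] run.
#'
#' @param lower,upper HRz boundaries; `lower < 0 < upper` required.
#' @param source `"fixed_2"` or `"empirical"`.
#' @return a `group_thresholds` list.
#' @export
group_thresholds <- function(lower = -2.0, upper = 2.0,
                             source = c("fixed_2", "empirical")) {
  source <- match.arg(source)
  if (!(lower < 0 && upper > 0)) {
    stop("need lower < 0 < upper", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, source = source),
    class = "group_thresholds"
  )
}

#' @rdname group_thresholds
#' @param calibration a [calibrate()] result whose empirical q025/q975
#'   become the boundaries.
#' @export
empirical_thresholds <- function(calibration) {
  stopifnot(inherits(calibration, "null_calibration"))
  group_thresholds(calibration$q025, calibration$q975, source = "empirical")
}

#' Classify screened features into survival groups
#'
#' A feature joins `OPCML_plus` (survival benefit under high relative
#' anchor expression) when its HRz falls below the lower boundary AND it
#' passes the significance-improvement filter; `GENEi_plus` symmetrically
#' above the upper boundary. Everything else — including features with
#' missing HRz or a failed filter — stays `ns`.
#'
#' @param records a [screen_all()] table with `hr_z` populated.
#' @param thresholds a [group_thresholds()].
#' @return the records with the `group` column filled in.
#' @export
classify_groups <- function(records, thresholds = group_thresholds()) {
  stopifnot(inherits(thresholds, "group_thresholds"))
  passes <- !is.na(records$passes_improvement) & records$passes_improvement
  z <- records$hr_z
  grp <- rep("ns", nrow(records))
  grp[!is.na(z) & z < thresholds$lower & passes] <- "OPCML_plus"
  grp[!is.na(z) & z > thresholds$upper & passes] <- "GENEi_plus"
  records$group <- grp
  records$skipped_reason[is.na(z) & is.na(records$skipped_reason)] <- "no_hrz"
  records
}
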