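#' Symmetrize a Cox hazard ratio about the null
#'
#' Raw hazard ratios are asymmetric about the no-effect value of 1: protective
#' effects are squeezed into (0, 1) while adverse effects range over
#' (1, Inf). `hr_sym()` maps an HR onto a scale that is symmetric about 0 by
#' inverting ratios below 1:
#'
#' \deqn{HRsym = \begin{cases} -1/HR + 1 & HR < 1 \\ HR - 1 & HR \ge 1
#' \end{cases}}
#'
#' so that `hr_sym(1) == 0`, `hr_sym(2) == 1`, `hr_sym(0.5) == -1`, and in
#' general `hr_sym(1/x) == -hr_sym(x)`. The transform is strictly increasing
#' and continuous at 1.
#'
#' @param cox_hr numeric vector of hazard ratios, all strictly positive.
#'   `NA` values pass through as `NA`.
#' @return numeric vector of symmetrized hazard ratios, 0 at HR = 1.
#' @seealso [z_standardize()] for the follow-on Z-scaling that yields HRz.
#' @examples
#' hr_sym(c(0.5, 1, 2))   # -1 0 1
#' @export
hr_sym <- function(cox_hr) {
  if (!is.numeric(cox_hr)) stop("`cox_hr` must be numeric", call. = FALSE)
  if (any(cox_hr <= 0, na.rm = TRUE)) {
    stop("hazard ratios must be strictly positive", call. = FALSE)
  }
  ifelse(cox_hr < 1, -1 / cox_hr + 1, cox_hr - 1)
}

#' Z-standardize symmetrized hazard ratios (HRz)
#'
#' Centers and scales a vector of `hr_sym` values with its own mean and
#' sample (n-1) standard deviation, so the screened population has mean 0
#' (the no-effect center) and sd 1. The standardization population should be
#' all non-skipped features of one screen — real or one randomized replicate —
#' never a mixture.
#'
#' @param hr_sym_values numeric vector with at least 2 finite values and
#'   nonzero variance. `NA`s are preserved in the output and excluded from
#'   the mean/sd.
#' @return an object of class `hrz_vector`: a list with `hr_z` (same length
#'   and names as the input), `hr_sym`, `mean_used` and `sd_used`.
#' @export
z_standardize <- function(hr_sym_values) {
  x <- hr_sym_values
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("need at least 2 finite values", call. = FALSE)
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero variance: cannot standardize", call. = FALSE)
  z <- (x - m) / s
  z[!ok] <- NA_real_
  structure(
    list(hr_z = z, hr_sym = x, mean_used = m, sd_used = s),
    class = "hrz_vector"
  )
}

#' @export
print.hrz_vector <- function(x, ...) {
  cat(sprintf(
    "<hrz_vector> %d values standardized with mean %.4g, sd %.4g\n",
    length(x$hr_z), x$mean_used, x$sd_used
  ))
  invisible(x)
}
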