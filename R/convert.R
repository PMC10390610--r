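# IFCC (mmol/mol) -> NGSP (%) master-equation constants.
# Location statistics use slope and intercept; dispersion statistics are
# translation-invariant, so only the slope applies.
.hba1c_slope <- 0.0915
.hba1c_intercept <- 2.15

.check_unit <- function(unit) {
  if (!all(unit %in% c("percent", "mmol_per_mol"))) {
    stop("unknown HbA1c unit: ", paste(setdiff(unique(unit), c("percent", "mmol_per_mol")), collapse = ", "),
         " (expected 'percent' or 'mmol_per_mol')", call. = FALSE)
  }
  invisible(unit)
}

#' Convert an HbA1c location statistic to the percent (NGSP) scale
#'
#' Means, medians, quartiles and confidence-interval bounds reported in
#' mmol/mol (IFCC) are mapped to percent by the affine master equation
#' HbA1c(%) = HbA1c(mmol/mol) x 0.0915 + 2.15. Values already in percent
#' are returned unchanged.
#'
#' @param value Numeric vector of location statistics.
#' @param unit `"percent"` or `"mmol_per_mol"`; recycled along `value`.
#' @return Numeric vector on the percent scale.
#' @examples
#' convert_location(66.1, "mmol_per_mol") # 8.198
#' convert_location(8.2, "percent")       # unchanged
#' @seealso [convert_dispersion()] for SDs and SEs.
#' @export
convert_location <- function(value, unit) {
  .check_unit(unit)
  unit <- rep_len(unit, length(value))
  ifelse(unit == "mmol_per_mol", value * .hba1c_slope + .hba1c_intercept, value)
}

#' Convert an HbA1c dispersion statistic to the percent scale
#'
#' Standard deviations and standard errors are invariant under the intercept
#' of the affine unit map, so mmol/mol values are multiplied by the slope
#' 0.0915 only.
#'
#' @param value Non-negative numeric vector (SD, SE, or interval half-width).
#' @param unit `"percent"` or `"mmol_per_mol"`; recycled along `value`.
#' @return Numeric vector on the percent scale.
#' @examples
#' convert_dispersion(10, "mmol_per_mol") # 0.915
#' convert_dispersion(16, "mmol_per_mol") # 1.464
#' @export
convert_dispersion <- function(value, unit) {
  .check_unit(unit)
  if (any(value < 0, na.rm = TRUE)) {
    stop("dispersion statistics must be non-negative", call. = FALSE)
  }
  unit <- rep_len(unit, length(value))
  ifelse(unit == "mmol_per_mol", value * .hba1c_slope, value)
}

#' Standard deviation from a standard error of the mean
#'
#' @param se Positive standard error(s) of the arm mean.
#' @param n Sample size(s), at least 2.
#' @return `se * sqrt(n)`.
#' @examples
#' sd_from_se(0.1, 100) # 1
#' @export
sd_from_se <- function(se, n) {
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive", call. = FALSE)
  if (any(n < 2, na.rm = TRUE)) stop("sample size must be at least 2", call. = FALSE)
  se * sqrt(n)
}

#' Standard deviation from a confidence interval for the mean
#'
#' Inverts the normal-theory interval mean +/- z * SD / sqrt(n): the SD is
#' sqrt(n) times the interval width over twice the standard-normal quantile
#' at (1 + level) / 2. Normal (not t) quantiles are used, the elementary
#' conversion convention.
#'
#' @param ci_low,ci_high Interval bounds, `ci_low < ci_high`.
#' @param n Sample size(s), at least 2.
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @return Positive SD estimate(s).
#' @examples
#' sd_from_ci(7.0, 7.784, n = 100) # 2.0
#' @export
sd_from_ci <- function(ci_low, ci_high, n, ci_level = 0.95) {
  if (any(n < 2, na.rm = TRUE)) stop("sample size must be at least 2", call. = FALSE)
  if (any(ci_level <= 0 | ci_level >= 1)) stop("ci_level must lie in (0, 1)", call. = FALSE)
  if (any(ci_high <= ci_low, na.rm = TRUE)) {
    stop("degenerate confidence interval: ci_low must be strictly below ci_high", call. = FALSE)
  }
  z <- stats::qnorm((1 + ci_level) / 2)
  sqrt(n) * (ci_high - ci_low) / (2 * z)
}

#' Mean and SD from medians, quartiles and/or extremes
#'
#' Estimates the sample mean by the optimal weighted combinations of Luo,
#' Wan, Lin and Chu (2018) and the SD by the closed-form quantile estimators
#' of Wan, Wang, Liu and Tong (2014), the defaults of the McGrath et al
#' estimation framework. Three reporting scenarios are supported:
#' `"min_med_max"` (minimum, median, maximum), `"q1_med_q3"` (quartiles and
#' median) and `"five_number"` (all five).
#'
#' @param scenario One of `"min_med_max"`, `"q1_med_q3"`, `"five_number"`.
#' @param n Sample size, at least 2.
#' @param median Sample median.
#' @param q1,q3 First and third quartiles (scenarios using quartiles).
#' @param min,max Sample extremes (scenarios using the range).
#' @return A list with components `mean` and `sd`.
#' @examples
#' mean_sd_from_quantiles("q1_med_q3", n = 100, median = 8, q1 = 7, q3 = 9)
#' @references
#' Luo D, Wan X, Liu J, Tong T (2018) Stat Methods Med Res 27:1785-1805.
#' Wan X, Wang W, Liu J, Tong T (2014) BMC Med Res Methodol 14:135.
#' @export
mean_sd_from_quantiles <- function(scenario = c("q1_med_q3", "min_med_max", "five_number"),
                                   n, median, q1 = NULL, q3 = NULL,
                                   min = NULL, max = NULL) {
  scenario <- match.arg(scenario)
  if (n < 2) stop("sample size must be at least 2", call. = FALSE)

  need <- switch(scenario,
    min_med_max = c(min = !is.null(min), max = !is.null(max)),
    q1_med_q3 = c(q1 = !is.null(q1), q3 = !is.null(q3)),
    five_number = c(min = !is.null(min), q1 = !is.null(q1),
                    q3 = !is.null(q3), max = !is.null(max))
  )
  if (!all(need)) {
    stop("scenario '", scenario, "' requires: ", paste(names(need)[!need], collapse = ", "),
         call. = FALSE)
  }
  ordered <- switch(scenario,
    min_med_max = min < median && median < max,
    q1_med_q3 = q1 <= median && median <= q3 && q1 < q3,
    five_number = min < q1 && q1 <= median && median <= q3 && q3 < max
  )
  if (!isTRUE(ordered)) stop("quantiles are not consistently ordered for '", scenario, "'",
                             call. = FALSE)

  # Wan et al closed-form expected ranges of normal order statistics
  xi_range <- 2 * stats::qnorm((n - 0.375) / (n + 0.25))
  xi_iqr <- 2 * stats::qnorm((0.75 * n - 0.125) / (n + 0.25))

  if (scenario == "min_med_max") {
    w <- 4 / (4 + n^0.75)
    mean <- w * (min + max) / 2 + (1 - w) * median
    sd <- (max - min) / xi_range
  } else if (scenario == "q1_med_q3") {
    w <- 0.7 + 0.39 / n
    mean <- w * (q1 + q3) / 2 + (1 - w) * median
    sd <- (q3 - q1) / xi_iqr
  } else {
    w1 <- 2.2 / (2.2 + n^0.75)
    w2 <- 0.7 - 0.72 / n^0.55
    mean <- w1 * (min + max) / 2 + w2 * (q1 + q3) / 2 + (1 - w1 - w2) * median
    sd <- ((max - min) / xi_range + (q3 - q1) / xi_iqr) / 2
  }
  list(mean = mean, sd = sd)
}

#' Back-transform a log(SD) value to the SD scale
#'
#' Exponentiates a (median) log(SD), optionally shifted by a model
#' coefficient, e.g. to express the fitted verum-placebo difference as an
#' absolute SD of HbA1c in percent.
#'
#' @param median_lnsd Log(SD) value, typically a group median.
#' @param delta Additive shift on the log scale (default 0), e.g. the
#'   treatment coefficient of the base model.
#' @return `exp(median_lnsd + delta)`.
#' @examples
#' backtransform_sd(0.10)        # 1.105
#' backtransform_sd(0.10, 0.037) # 1.147
#' @export
backtransform_sd <- function(median_lnsd, delta = 0) {
  exp(median_lnsd + delta)
}
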