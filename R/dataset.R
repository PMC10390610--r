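#' Assemble normalised arm records into a meta-analysis dataset
#'
#' Groups arm records by trial and tags the outcome track. The base
#' treatment-contrast model needs trials with both a placebo and a verum
#' arm; trials whose arms all share one treatment level are retained (they
#' still inform the trial-intercept variance and the log-mean effect) and
#' counted in `n_trials_mixed` separately.
#'
#' @param records Data frame of normalised arm records (see
#'   [make_arm_record()]) or an `arm_records` object.
#' @param track `"raw"` or `"baseline_corrected"`.
#' @return An object of class `meta_dataset`: list with `records`, `track`,
#'   `n_trials`, `n_arms`, `n_trials_mixed`.
#' @export
meta_dataset <- function(records, track = c("raw", "baseline_corrected")) {
  track <- match.arg(track)
  if (inherits(records, "arm_records")) records <- records$records
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("trial_id", "arm_id", "treatment", "n", "mean_pct", "sd_pct",
              "lnsd_bc", "weight", "log_mean")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records are missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(records) == 0) stop("empty record set", call. = FALSE)
  if (any(records$weight <= 0)) stop("weights must be positive", call. = FALSE)
  mixed <- tapply(records$treatment, records$trial_id,
                  function(t) any(t == "placebo") && any(t == "verum"))
  structure(list(records = records, track = track,
                 n_trials = length(unique(records$trial_id)),
                 n_arms = nrow(records),
                 n_trials_mixed = sum(mixed)),
            class = "meta_dataset")
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("Meta-analysis dataset (", x$track, " log(SD) track)\n", sep = "")
  cat("  ", x$n_arms, " arms from ", x$n_trials, " trials (",
      x$n_trials_mixed, " with both treatment levels)\n", sep = "")
  cat("  ", sum(x$records$treatment == "verum"), " verum / ",
      sum(x$records$treatment == "placebo"), " placebo arms\n", sep = "")
  invisible(x)
}

.describe_one <- function(x) {
  ok <- !is.na(x)
  q <- stats::quantile(x[ok], c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(n_missing = sum(!ok), median = q[3], min = q[1], q1 = q[2], q3 = q[4], max = q[5])
}

#' Descriptive summary of a meta-analysis dataset by treatment group
#'
#' For each variable and treatment group, reports the median with minimum,
#' quartiles and maximum (quantiles by linear interpolation between order
#' statistics, `type = 7`) and the number of arms missing the variable,
#' plus counts of verum arms per drug class. `lnsd` is the uncorrected
#' log(SD); `lnsd_bc` adds the small-sample bias term.
#'
#' @param dataset A `meta_dataset`.
#' @return A list of class `meta_descriptives`: `by_treatment` (data frame,
#'   one row per variable x group) and `drug_class_counts`.
#' @export
run_descriptives <- function(dataset) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rec <- dataset$records
  rec$lnsd <- log(rec$sd_pct)
  vars <- c("age_years", "male_pct", "bmi", "disease_duration_years",
            "baseline_hba1c_pct", "year", "trial_duration_weeks",
            "n", "mean_pct", "log_mean", "sd_pct", "lnsd", "lnsd_bc")
  vars <- vars[vars %in% names(rec)]
  rows <- list()
  for (grp in c("placebo", "verum")) {
    sub <- rec[rec$treatment == grp, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (v in vars) {
      if (all(is.na(sub[[v]]))) next
      d <- .describe_one(sub[[v]])
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = grp, variable = v, n_arms = nrow(sub),
        n_missing = d[["n_missing"]], median = d[["median"]], min = d[["min"]],
        q1 = d[["q1"]], q3 = d[["q3"]], max = d[["max"]],
        stringsAsFactors = FALSE)
    }
  }
  verum <- rec[rec$treatment == "verum", , drop = FALSE]
  cls <- if (nrow(verum) && "drug_class" %in% names(verum)) {
    as.data.frame(table(drug_class = verum$drug_class), stringsAsFactors = FALSE)
  } else {
    data.frame(drug_class = character(), Freq = integer())
  }
  names(cls)[names(cls) == "Freq"] <- "n_arms"
  structure(list(by_treatment = do.call(rbind, rows), drug_class_counts = cls),
            class = "meta_descriptives")
}

#' @export
print.meta_descriptives <- function(x, digits = 2, ...) {
  df <- x$by_treatment
  cat("Arm-level descriptives: median (min/Q1/Q3/max), by treatment group\n")
  for (grp in unique(df$treatment)) {
    cat("\n", grp, " arms (N = ", df$n_arms[df$treatment == grp][1], "):\n", sep = "")
    sub <- df[df$treatment == grp, ]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      cat(sprintf("  %-24s %s (%s/%s/%s/%s), missing %d\n", r$variable,
                  format(round(r$median, digits)), format(round(r$min, digits)),
                  format(round(r$q1, digits)), format(round(r$q3, digits)),
                  format(round(r$max, digits)), r$n_missing))
    }
  }
  if (nrow(x$drug_class_counts)) {
    cat("\nverum arms per drug class:\n")
    for (i in seq_len(nrow(x$drug_class_counts))) {
      cat(sprintf("  %-30s %d\n", x$drug_class_counts$drug_class[i],
                  x$drug_class_counts$n_arms[i]))
    }
  }
  invisible(x)
}
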