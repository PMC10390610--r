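# Canonical arm-report schema. One row per trial arm, summaries as reported.
.report_cols <- c("trial_id", "arm_id", "treatment", "drug_class", "n", "unit",
                  "mean", "sd", "se", "ci_low", "ci_high", "ci_level",
                  "median", "q1", "q3", "min", "max",
                  "age_years", "male_pct", "bmi", "disease_duration_years",
                  "baseline_hba1c_pct", "trial_duration_weeks", "year", "track")

.covariate_cols <- c("age_years", "male_pct", "bmi", "disease_duration_years",
                     "baseline_hba1c_pct", "trial_duration_weeks", "year")

.drug_classes <- c("alpha-glucosidase inhibitors", "DPP-4 inhibitors",
                   "GLP-1 receptor agonists", "metformin", "SGLT-2 inhibitors",
                   "sulfonylureas", "thiazolidinediones", "combination",
                   "other", "placebo")

.col_or_na <- function(df, col) {
  if (col %in% names(df)) df[[col]] else rep(NA, nrow(df))
}

#' Read arm-level summary reports from delimited text
#'
#' Reads one row per trial arm from a comma- (`.csv`) or tab-separated
#' (`.tsv`, `.txt`) file. A column mapping translates the file's native
#' headers to the canonical schema (`trial_id`, `arm_id`, `treatment`,
#' `drug_class`, `n`, `unit`, `mean`, `sd`, `se`, `ci_low`, `ci_high`,
#' `ci_level`, `median`, `q1`, `q3`, `min`, `max`, the baseline covariates,
#' and `track`), so externally deposited datasets can be ingested without
#' code changes.
#'
#' @param path Path to the delimited file (UTF-8, decimal point `.`).
#' @param mapping Optional column mapping: a named character vector or list
#'   (canonical name -> column name in the file), or a path to a YAML/JSON
#'   file holding one.
#' @return A data frame in the canonical arm-report schema. Canonical
#'   columns absent from the file are filled with `NA`.
#' @export
read_arm_reports <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
      mapping <- if (grepl("\\.json$", mapping, ignore.case = TRUE)) {
        jsonlite::read_json(mapping, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(mapping)
      }
    }
    mapping <- unlist(mapping)
    missing_src <- setdiff(unname(mapping), names(df))
    if (length(missing_src)) {
      stop("mapped column(s) not present in ", path, ": ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(mapping)) names(df)[names(df) == mapping[[canon]]] <- canon
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (col in .report_cols) out[[col]] <- .col_or_na(df, col)
  out
}

# Resolve one arm's SD (and, if needed, mean) from the reported statistics,
# least-derived representation first: sd > se > ci > quantiles.
.resolve_sd <- function(row) {
  if (!is.na(row$sd)) return(list(sd = row$sd, mean = row$mean, via = "sd"))
  if (!is.na(row$se) && !is.na(row$n)) {
    return(list(sd = sd_from_se(row$se, row$n), mean = row$mean, via = "se"))
  }
  if (!is.na(row$ci_low) && !is.na(row$ci_high) && !is.na(row$n)) {
    lev <- if (is.na(row$ci_level)) 0.95 else row$ci_level
    return(list(sd = sd_from_ci(row$ci_low, row$ci_high, row$n, lev),
                mean = row$mean, via = "ci"))
  }
  has <- function(x) !is.na(x)
  scen <- if (has(row$median) && has(row$q1) && has(row$q3) && has(row$min) && has(row$max)) {
    "five_number"
  } else if (has(row$median) && has(row$q1) && has(row$q3)) {
    "q1_med_q3"
  } else if (has(row$median) && has(row$min) && has(row$max)) {
    "min_med_max"
  } else {
    return(NULL)
  }
  if (is.na(row$n)) return(NULL)
  est <- mean_sd_from_quantiles(scen, n = row$n, median = row$median,
                                q1 = row$q1, q3 = row$q3,
                                min = row$min, max = row$max)
  mean <- if (!is.na(row$mean)) row$mean else est$mean
  list(sd = est$sd, mean = mean, via = paste0("quantiles:", scen))
}

#' Normalise reported arm summaries into analysis records
#'
#' Turns arm reports (any mix of SD, SE, confidence interval or quantile
#' reporting, percent or mmol/mol) into the normalised analysis rows used by
#' the meta-regression: percent-scale mean and SD, the bias-corrected
#' outcome `lnsd_bc = log(sd_pct) + 1/(2n - 1)`, the inverse-variance weight
#' `2n - 1`, and `log_mean = log(mean_pct)`. The bias term removes the
#' small-sample downward bias of the log sample SD; its inverse variance is
#' the weight. Arms whose SD, mean or sample size cannot be resolved are
#' excluded, never imputed, and every exclusion is logged with a reason
#' code.
#'
#' @param report Data frame of arm reports in the canonical schema (see
#'   [read_arm_reports()]); a single row is fine.
#' @param weight_scheme `"2n-1"` (default), the inverse variance of the
#'   bias-corrected log(SD); or `"2(n-1)"`, the reciprocal of the common
#'   large-sample variance of an uncorrected log(SD). The alternative is
#'   provided for sensitivity analysis only and is never substituted
#'   silently.
#' @return An object of class `arm_records`: a list with `records` (data
#'   frame of normalised rows, including the resolution route `sd_via`) and
#'   `exclusions` (data frame with `trial_id`, `arm_id`, `reason`).
#' @examples
#' rep <- data.frame(trial_id = "t1", arm_id = "a1", treatment = "verum",
#'                   drug_class = "metformin", n = 83, unit = "percent",
#'                   mean = 7.3, sd = 1.10, track = "raw")
#' make_arm_record(rep)$records$lnsd_bc # log(1.10) + 1/165
#' @export
make_arm_record <- function(report, weight_scheme = c("2n-1", "2(n-1)")) {
  weight_scheme <- match.arg(weight_scheme)
  df <- as.data.frame(report, stringsAsFactors = FALSE)
  for (col in .report_cols) if (!col %in% names(df)) df[[col]] <- NA
  bad_trt <- !df$treatment %in% c("placebo", "verum")
  if (any(bad_trt)) {
    stop("treatment must be 'placebo' or 'verum'; offending arm(s): ",
         paste(df$arm_id[bad_trt], collapse = ", "), call. = FALSE)
  }

  recs <- vector("list", nrow(df))
  excl <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    reason <- NULL
    if (is.na(row$n)) {
      reason <- "missing_n"
    } else if (row$n < 2) {
      reason <- "n_below_2"
    }
    res <- if (is.null(reason)) .resolve_sd(row) else NULL
    if (is.null(reason) && is.null(res)) reason <- "no_variability_statistic"
    if (is.null(reason) && (is.null(res$mean) || is.na(res$mean))) reason <- "missing_mean"
    if (is.null(reason)) {
      unit <- if (is.na(row$unit)) "percent" else row$unit
      mean_pct <- convert_location(res$mean, unit)
      sd_pct <- convert_dispersion(res$sd, unit)
      if (!is.finite(sd_pct) || sd_pct <= 0) {
        reason <- "nonpositive_sd"
      } else if (!is.finite(mean_pct) || mean_pct <= 0) {
        reason <- "nonpositive_mean"
      }
    }
    if (!is.null(reason)) {
      excl[[i]] <- data.frame(trial_id = row$trial_id, arm_id = row$arm_id,
                              reason = reason, stringsAsFactors = FALSE)
      next
    }
    w <- if (weight_scheme == "2n-1") 2 * row$n - 1 else 2 * (row$n - 1)
    recs[[i]] <- data.frame(
      trial_id = row$trial_id, arm_id = row$arm_id, treatment = row$treatment,
      drug_class = if (is.na(row$drug_class)) {
        if (row$treatment == "placebo") "placebo" else "other"
      } else row$drug_class,
      n = row$n, mean_pct = mean_pct, sd_pct = sd_pct,
      lnsd_bc = log(sd_pct) + 1 / (2 * row$n - 1),
      weight = w, log_mean = log(mean_pct),
      age_years = row$age_years, male_pct = row$male_pct, bmi = row$bmi,
      disease_duration_years = row$disease_duration_years,
      baseline_hba1c_pct = row$baseline_hba1c_pct,
      trial_duration_weeks = row$trial_duration_weeks, year = row$year,
      track = if (is.na(row$track)) "raw" else row$track,
      sd_via = res$via, stringsAsFactors = FALSE
    )
  }
  structure(list(records = do.call(rbind, recs[!vapply(recs, is.null, TRUE)]),
                 exclusions = do.call(rbind, excl[!vapply(excl, is.null, TRUE)])),
            class = "arm_records")
}

#' @export
print.arm_records <- function(x, ...) {
  n_rec <- if (is.null(x$records)) 0L else nrow(x$records)
  n_exc <- if (is.null(x$exclusions)) 0L else nrow(x$exclusions)
  cat("Normalised arm records:", n_rec, "retained,", n_exc, "excluded\n")
  if (n_exc > 0) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat("  excluded (", r, "): ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Write normalised arm records as tab-separated text
#'
#' @param x An `arm_records` object or its `records` data frame.
#' @param path Output path.
#' @export
write_arm_records <- function(x, path) {
  df <- if (inherits(x, "arm_records")) x$records else x
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the exclusion log, one JSON object per excluded arm
#'
#' @param x An `arm_records` object or its `exclusions` data frame.
#' @param path Output path (newline-delimited JSON).
#' @export
write_exclusion_log <- function(x, path) {
  df <- if (inherits(x, "arm_records")) x$exclusions else x
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(df)) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
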