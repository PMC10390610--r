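# End-to-end orchestration: ingest -> normalise -> fit all models -> report.

.default_predictors <- c("age_years", "male_pct", "bmi", "disease_duration_years",
                         "baseline_hba1c_pct", "trial_duration_weeks", "year")

.fit_to_list <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       ci = apply(fit$ci, 1, function(r) list(low = r[[1]], high = r[[2]])),
       tau2 = fit$tau2,
       tau2_ci = list(low = fit$tau2_ci[1], high = fit$tau2_ci[2]),
       sigma2 = fit$sigma2, loglik = fit$loglik, method = fit$method,
       n_arms_used = fit$n_arms_used, n_trials_used = fit$n_trials_used,
       n_arms_dropped = fit$n_arms_dropped, converged = fit$converged)
}

.interaction_to_list <- function(ir) {
  sl <- function(s) list(estimate = s[["estimate"]], ci_low = s[["ci_low"]],
                         ci_high = s[["ci_high"]])
  list(predictor = ir$predictor, slope_verum = sl(ir$slope_verum),
       slope_placebo = sl(ir$slope_placebo),
       slope_difference = sl(ir$slope_difference),
       n_missing_arms = ir$n_missing_arms, fit = .fit_to_list(ir$fit))
}

.log_model <- function(label, fit, verbose) {
  if (verbose) {
    message(sprintf("model=%s n_arms_used=%d n_trials_used=%d converged=%s",
                    label, fit$n_arms_used, fit$n_trials_used, fit$converged))
  }
}

#' Aligned-text table of treatment-by-predictor interaction results
#'
#' @param interactions List of `lnsd_interaction` objects.
#' @param digits Decimals shown.
#' @return Character vector of lines (one header, one row per predictor).
#' @export
format_interaction_table <- function(interactions, digits = 3) {
  fmt <- function(s) sprintf("%.*f (%.*f, %.*f)", digits, s[[1]], digits, s[[2]],
                             digits, s[[3]])
  lines <- sprintf("%-26s %8s %-24s %-24s %-24s", "predictor", "missing",
                   "slope verum (CI)", "slope placebo (CI)", "difference (CI)")
  for (ir in interactions) {
    lines <- c(lines, sprintf("%-26s %8d %-24s %-24s %-24s", ir$predictor,
                              ir$n_missing_arms, fmt(ir$slope_verum),
                              fmt(ir$slope_placebo), fmt(ir$slope_difference)))
  }
  lines
}

#' Aligned-text table of drug-class contrasts vs placebo
#'
#' @param contrasts An `lnsd_contrasts` object.
#' @param digits Decimals shown.
#' @return Character vector of lines.
#' @export
format_contrast_table <- function(contrasts, digits = 3) {
  df <- contrasts$contrasts
  lines <- sprintf("%-30s %6s %-24s", "drug class", "arms", "difference vs placebo (CI)")
  for (i in seq_len(nrow(df))) {
    lines <- c(lines, sprintf("%-30s %6d %.*f (%.*f, %.*f)%s", df$drug_class[i],
                              df$n_arms[i], digits, df$estimate[i], digits,
                              df$ci_low[i], digits, df$ci_high[i],
                              if (df$unstable[i]) "  [unstable]" else ""))
  }
  lines
}

#' Run the full variability meta-regression analysis on one dataset
#'
#' Executes, in order: the base treatment-contrast model, one interaction
#' model per continuous predictor, the drug-class model, the interaction
#' analysis in a drug-class subgroup, and the variance-of-means
#' corridor-effect check. Results are returned as a bundle and, when
#' `output_dir` is given, written as JSON plus aligned-text tables. Any
#' model failure propagates as an error (never a silent partial bundle).
#'
#' @param dataset A [meta_dataset()], or a path to a delimited arm-report
#'   file to be ingested via [read_arm_reports()] and [make_arm_record()].
#' @param mapping Optional column mapping when `dataset` is a path.
#' @param track Outcome track tag when `dataset` is a path.
#' @param predictors Continuous predictors for the interaction models;
#'   defaults to the seven arm-level covariates (drug class enters through
#'   its own model). Predictors missing on every arm are reported as
#'   errors.
#' @param subgroup_class Drug class for the subgroup interaction analysis
#'   (default `"GLP-1 receptor agonists"`); skipped (with a log line) when
#'   the class is absent from the data.
#' @param subgroup_predictor Predictor for the subgroup analysis (default
#'   baseline HbA1c).
#' @param ci_level,method Passed to the fitters.
#' @param output_dir Optional directory for `results.json`,
#'   `interactions.txt`, `drug_class_contrasts.txt`,
#'   `descriptives.txt` and, when ingesting from file, the exclusion log.
#' @param verbose One structured log line per model (default TRUE).
#' @return A list of class `lnsd_analysis`: `dataset` counts, `base`,
#'   `interactions`, `drug_class`, `subgroup`, `variance_of_means`,
#'   `descriptives`, `exclusions`.
#' @export
run_full_analysis <- function(dataset, mapping = NULL,
                              track = c("raw", "baseline_corrected"),
                              predictors = .default_predictors,
                              subgroup_class = "GLP-1 receptor agonists",
                              subgroup_predictor = "baseline_hba1c_pct",
                              ci_level = 0.95, method = "REML",
                              output_dir = NULL, verbose = TRUE) {
  track <- match.arg(track)
  exclusions <- NULL
  if (is.character(dataset)) {
    reports <- read_arm_reports(dataset, mapping)
    norm <- make_arm_record(reports)
    exclusions <- norm$exclusions
    dataset <- meta_dataset(norm, track = track)
    if (verbose) {
      message(sprintf("ingest: %d arms read, %d retained, %d excluded",
                      nrow(reports), dataset$n_arms,
                      if (is.null(exclusions)) 0L else nrow(exclusions)))
    }
  }
  stopifnot(inherits(dataset, "meta_dataset"))

  base <- fit_base_model(dataset, method = method, ci_level = ci_level)
  .log_model("base", base, verbose)

  interactions <- list()
  for (p in predictors) {
    ir <- fit_interaction_model(dataset, p, method = method, ci_level = ci_level)
    .log_model(paste0("interaction:", p), ir$fit, verbose)
    interactions[[p]] <- ir
  }

  drug_class <- fit_drugclass_model(dataset, method = method, ci_level = ci_level)
  .log_model("drug_class", drug_class$fit, verbose)

  subgroup <- NULL
  if (subgroup_class %in% dataset$records$drug_class) {
    subgroup <- fit_subgroup(dataset, subgroup_class, subgroup_predictor,
                             method = method, ci_level = ci_level)
    .log_model(paste0("subgroup:", subgroup_class), subgroup$fit, verbose)
  } else if (verbose) {
    message("subgroup skipped: no arms of class '", subgroup_class, "'")
  }

  vom <- variance_of_means(dataset, ci_level = ci_level)
  desc <- run_descriptives(dataset)

  bundle <- structure(list(
    dataset = list(track = dataset$track, n_arms = dataset$n_arms,
                   n_trials = dataset$n_trials,
                   n_excluded = if (is.null(exclusions)) 0L else nrow(exclusions)),
    base = base, interactions = interactions, drug_class = drug_class,
    subgroup = subgroup, variance_of_means = vom, descriptives = desc,
    exclusions = exclusions), class = "lnsd_analysis")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    json <- list(
      dataset = bundle$dataset,
      base = .fit_to_list(base),
      interactions = lapply(interactions, .interaction_to_list),
      drug_class = list(contrasts = drug_class$contrasts,
                        fit = .fit_to_list(drug_class$fit)),
      subgroup = if (!is.null(subgroup)) .interaction_to_list(subgroup),
      variance_of_means = vom)
    jsonlite::write_json(json, file.path(output_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    writeLines(format_interaction_table(interactions),
               file.path(output_dir, "interactions.txt"))
    writeLines(format_contrast_table(drug_class),
               file.path(output_dir, "drug_class_contrasts.txt"))
    utils::capture.output(print(desc),
                          file = file.path(output_dir, "descriptives.txt"))
    if (!is.null(exclusions)) {
      write_exclusion_log(exclusions, file.path(output_dir, "exclusions.ndjson"))
    }
  }
  bundle
}

#' @export
print.lnsd_analysis <- function(x, digits = 3, ...) {
  cat("Variability meta-regression bundle (", x$dataset$track, " track): ",
      x$dataset$n_arms, " arms / ", x$dataset$n_trials, " trials\n\n", sep = "")
  print(x$base, digits = digits)
  cat("\n")
  writeLines(format_interaction_table(x$interactions, digits = digits))
  cat("\n")
  writeLines(format_contrast_table(x$drug_class, digits = digits))
  if (!is.null(x$subgroup)) {
    cat("\nSubgroup analysis:\n")
    print(x$subgroup, digits = digits)
  }
  cat("\nVariance of arm mean HbA1c (corridor-effect check):\n")
  print(x$variance_of_means, digits = digits)
  invisible(x)
}
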