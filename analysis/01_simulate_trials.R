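#!/usr/bin/env Rscript

# Individual-level mechanism study: how person-level treatment
# heterogeneity shows up (or hides) in arm-level SDs of HbA1c after
# treatment. Three fictitious but realistic 100-per-arm trials:
#   (a) a treatment effect but no heterogeneity  -> equal after SDs
#   (b) a responder mixture (half "super responders") -> inflated verum SD
#   (c) the same mixture, but benefit rank-coupled against the would-be
#       outcome -> the SD signal is masked despite real heterogeneity
# Writes results/individual_trial_sds.csv.

suppressPackageStartupMessages(library(armvar))
dir.create("results", showWarnings = FALSE)

p <- 0.5
d <- -sqrt(112 / (p * (1 - p))) # p(1-p)d^2 = 16^2 - 12^2 on the mmol/mol scale

scenarios <- list(
  homogeneous = individual_trial_config(n_per_arm = 100, seed = 101),
  responder_mixture = individual_trial_config(
    n_per_arm = 100, nonresponder_fraction = p, responder_extra_effect = d,
    seed = 101),
  rank_coupled_mixture = individual_trial_config(
    n_per_arm = 100, nonresponder_fraction = p, responder_extra_effect = d,
    responder_assignment = "rank_coupled", seed = 101)
)

rows <- list()
for (nm in names(scenarios)) {
  sim <- simulate_individual_trial(scenarios[[nm]])
  rep <- sim$reports_raw
  rows[[nm]] <- data.frame(
    scenario = nm, treatment = rep$treatment, n = rep$n,
    mean_mmol = round(rep$mean, 1), sd_mmol = round(rep$sd, 1),
    sd_pct = round(convert_dispersion(rep$sd, "mmol_per_mol"), 2),
    sd_change_mmol = round(sim$reports_baseline_corrected$sd, 1))
  cat(sprintf("%-22s placebo SD %5.1f | verum SD %5.1f mmol/mol\n", nm,
              rep$sd[rep$treatment == "placebo"],
              rep$sd[rep$treatment == "verum"]))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/individual_trial_sds.csv", row.names = FALSE)

cat("\nAt n = 100 per arm the homogeneous trial shows near-equal SDs (~12",
    "mmol/mol), the random responder mixture inflates the verum SD towards",
    "16 mmol/mol, and the rank-coupled mixture hides the same person-level",
    "heterogeneity inside an ordinary-looking SD - the known blind spot of",
    "variability-based detection.\n")
cat("wrote results/individual_trial_sds.csv\n")
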