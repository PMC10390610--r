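#!/usr/bin/env Rscript

# Meta-regression at the published design scale (174 trials, one placebo
# plus one to three verum arms, arm sizes 5 to 8078), in two runs.
#
# Run A: data generated from the base model itself (treatment contrast
#   0.037 in log(SD), log-mean effect 1.476, trial-intercept variance
#   0.112, inverse-variance residual scale 1). The fit should recover the
#   generating values, sigma2 should sit near 1, and the back-transformed
#   SDs illustrate what the contrast means on the percent scale.
#
# Run B: the same design with two planted signals - a raw-scale
#   disease-duration-by-treatment interaction of 0.011 per year and extra
#   log(SD) inflation of 0.15 for the GLP-1 receptor agonist class. The
#   full pipeline should flag exactly these two: the duration slope
#   difference near 0.011 and an elevated GLP-1 contrast. Because the
#   planted interaction acts on the raw duration scale (mean ~7.6 years),
#   it also lifts the marginal verum-placebo contrast of the deliberately
#   misspecified base model, and the unmodelled class structure inflates
#   its residual scale - both visible below, neither a defect.
#
# Writes results/full_analysis/ (JSON + aligned-text tables).

suppressPackageStartupMessages(library(armvar))

cat("=== Run A: base-model data, base-model fit ===\n")
ds_a <- simulate_meta_dataset(meta_sim_config(seed = 314159))
fit_a <- fit_base_model(ds_a)
print(fit_a)

b_t <- unname(coef(fit_a)["treatment_verum"])
rec_a <- ds_a$records
med_p <- median(log(rec_a$sd_pct[rec_a$treatment == "placebo"]))
cat(sprintf(
  "\nA placebo-arm median log(SD) of %.2f is an SD of %.3f%%; adding the fitted\n",
  med_p, backtransform_sd(med_p)))
cat(sprintf(
  "treatment contrast %.3f raises it to %.3f%% - a small absolute difference.\n",
  b_t, backtransform_sd(med_p, b_t)))
cat(sprintf(
  "sigma2 = %.2f, close to 1: the residual scale is consistent with the\ninverse-variance interpretation of the 2n-1 weights here.\n",
  fit_a$sigma2))

cat("\n=== Run B: planted duration interaction + GLP-1 inflation ===\n")
cfg_b <- meta_sim_config(
  seed = 271830,
  interaction_betas = c(disease_duration_years = 0.011))
ds_b <- simulate_meta_dataset(cfg_b)
rec <- ds_b$records
glp <- rec$drug_class == "GLP-1 receptor agonists"
rec$lnsd_bc[glp] <- rec$lnsd_bc[glp] + 0.15
rec$sd_pct[glp] <- rec$sd_pct[glp] * exp(0.15)
ds_b <- meta_dataset(rec, "raw")

bundle <- run_full_analysis(ds_b, output_dir = "results/full_analysis")
print(bundle)

dd <- bundle$interactions[["disease_duration_years"]]
con <- bundle$drug_class$contrasts
cat(sprintf(
  "\nRecovered duration slope difference: %.3f (planted 0.011).\n",
  dd$slope_difference[["estimate"]]))
cat(sprintf(
  "GLP-1 contrast %.2f vs median other-class contrast %.2f: the planted class\nsignal stands out by about the planted 0.15.\n",
  con$estimate[con$drug_class == "GLP-1 receptor agonists"],
  median(con$estimate[con$drug_class != "GLP-1 receptor agonists"])))
cat("wrote results/full_analysis/\n")
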