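#!/usr/bin/env Rscript

# Simulation-based validation of the weighted random-intercept REML
# fitter at the full design scale: 200 replicates of simulate -> fit with
# the study-scale generating parameters, summarising bias, RMSE and 95%
# interval coverage for the treatment contrast, the log-mean effect and
# the trial-intercept variance.
# Writes results/parameter_recovery.csv.

suppressPackageStartupMessages(library(armvar))
dir.create("results", showWarnings = FALSE)

cfg <- meta_sim_config(seed = 271828)
tab <- parameter_recovery(cfg, n_reps = 200, tau2_ci = TRUE)
print(tab, digits = 4)
write.csv(tab, "results/parameter_recovery.csv", row.names = FALSE)

ok_bias <- all(abs(tab$bias) < 3 * tab$mcse)
ok_cov <- all(tab$coverage > 0.9 & tab$coverage < 0.99)
cat(sprintf("\nbias within 3 Monte-Carlo SEs for every parameter: %s\n", ok_bias))
cat(sprintf("interval coverage near the nominal 95%% for every parameter: %s\n", ok_cov))
cat(sprintf("non-converged replicates: %d of %d\n", tab$n_nonconverged[1], tab$n_reps[1]))
cat("wrote results/parameter_recovery.csv\n")
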