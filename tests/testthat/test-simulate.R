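test_that("individual-level configs are validated", {
  expect_error(individual_trial_config(n_per_arm = 1), "at least 2")
  expect_error(individual_trial_config(baseline_sd = 0), "positive")
  expect_error(individual_trial_config(nonresponder_fraction = 1.2), "\\[0, 1\\]")
})

test_that("without a responder mixture both arms share the after-treatment SD", {
  cfg <- individual_trial_config(n_per_arm = 20000, seed = 201)
  sim <- simulate_individual_trial(cfg)
  sd_p <- sim$reports_raw$sd[sim$reports_raw$treatment == "placebo"]
  sd_v <- sim$reports_raw$sd[sim$reports_raw$treatment == "verum"]
  target <- sqrt(cfg$baseline_sd^2 + cfg$residual_change_sd^2) # 12 mmol/mol
  expect_equal(target, 12)
  expect_equal(sd_p, target, tolerance = 0.02)
  expect_equal(sd_v, target, tolerance = 0.02)
  # the verum arm still has the stronger mean reduction (a treatment effect
  # is not treatment heterogeneity)
  expect_lt(sim$reports_raw$mean[sim$reports_raw$treatment == "verum"],
            sim$reports_raw$mean[sim$reports_raw$treatment == "placebo"])
})

test_that("responder mixture inflates the verum SD by the analytic amount", {
  # p(1-p) d^2 = 112 on top of a 12 mmol/mol base gives a 16 mmol/mol SD
  p <- 0.5
  d <- -sqrt(112 / (p * (1 - p)))
  cfg <- individual_trial_config(n_per_arm = 10000, nonresponder_fraction = p,
                                 responder_extra_effect = d, seed = 202)
  sim <- simulate_individual_trial(cfg)
  sd_v <- sim$reports_raw$sd[sim$reports_raw$treatment == "verum"]
  expect_equal(sqrt(12^2 + p * (1 - p) * d^2), 16)
  expect_equal(sd_v, 16, tolerance = 0.5 / 16)
  sd_p <- sim$reports_raw$sd[sim$reports_raw$treatment == "placebo"]
  expect_equal(sd_p, 12, tolerance = 0.5 / 12)
  # empirical mixture-variance identity at 2% relative error
  expect_lt(abs(sd_v^2 / (12^2 + p * (1 - p) * d^2) - 1), 0.02)
  # change-score track: baseline variance does not propagate
  sd_vc <- sim$reports_baseline_corrected$sd[
    sim$reports_baseline_corrected$treatment == "verum"]
  expect_equal(sd_vc, sqrt(cfg$residual_change_sd^2 + p * (1 - p) * d^2),
               tolerance = 0.05)
})

test_that("rank-coupled responder assignment can mask heterogeneity in the SDs", {
  p <- 0.5
  d <- -sqrt(112 / (p * (1 - p)))
  random <- simulate_individual_trial(individual_trial_config(
    n_per_arm = 10000, nonresponder_fraction = p, responder_extra_effect = d,
    responder_assignment = "random", seed = 203))
  coupled <- simulate_individual_trial(individual_trial_config(
    n_per_arm = 10000, nonresponder_fraction = p, responder_extra_effect = d,
    responder_assignment = "rank_coupled", seed = 203))
  sd_random <- random$reports_raw$sd[random$reports_raw$treatment == "verum"]
  sd_coupled <- coupled$reports_raw$sd[coupled$reports_raw$treatment == "verum"]
  # person-level heterogeneity is identical, yet the negative dependence
  # compresses the verum SD back towards (or below) the placebo value
  expect_lt(sd_coupled, sd_random - 2)
  expect_lt(sd_coupled, 13)
})

test_that("simulations are bit-identical under a repeated seed", {
  cfg <- individual_trial_config(n_per_arm = 500, nonresponder_fraction = 0.3,
                                 responder_extra_effect = -10, seed = 204)
  s1 <- simulate_individual_trial(cfg)
  s2 <- simulate_individual_trial(cfg)
  expect_identical(s1, s2)
  cfg2 <- individual_trial_config(n_per_arm = 500, nonresponder_fraction = 0.3,
                                  responder_extra_effect = -10, seed = 205)
  expect_false(identical(simulate_individual_trial(cfg2)$individuals$after,
                         s1$individuals$after))

  mcfg <- meta_sim_config(n_trials = 30, seed = 206)
  expect_identical(simulate_meta_dataset(mcfg), simulate_meta_dataset(mcfg))
})

test_that("the arm reports of a simulated trial flow through normalisation", {
  sim <- simulate_individual_trial(individual_trial_config(n_per_arm = 300, seed = 207))
  out <- make_arm_record(sim$reports_raw)
  expect_equal(nrow(out$records), 2)
  expect_null(out$exclusions)
  expect_equal(out$records$sd_pct, sim$reports_raw$sd * 0.0915, tolerance = 1e-12)
  expect_equal(out$records$weight, 2 * sim$reports_raw$n - 1)
})

test_that("with vanishing variances the arm-level outcome is exactly linear", {
  cfg <- meta_sim_config(n_trials = 20, tau2 = 0, sigma2 = 1e-12, seed = 208)
  ds <- simulate_meta_dataset(cfg)
  rec <- ds$records
  eta <- cfg$beta0 + cfg$beta_t * (rec$treatment == "verum") + cfg$beta_m * rec$log_mean
  expect_equal(rec$lnsd_bc, eta, tolerance = 1e-4)
})

test_that("trial-level residual variance matches the generating tau2", {
  cfg <- meta_sim_config(n_trials = 800, sigma2 = 1e-8, seed = 209)
  ds <- simulate_meta_dataset(cfg)
  rec <- ds$records
  resid <- rec$lnsd_bc - (cfg$beta0 + cfg$beta_t * (rec$treatment == "verum") +
                            cfg$beta_m * rec$log_mean)
  u_hat <- tapply(resid, rec$trial_id, mean)
  expect_equal(var(u_hat), cfg$tau2, tolerance = 0.1)
})

test_that("simulated records are internally coherent analysis rows", {
  ds <- simulate_meta_dataset(meta_sim_config(n_trials = 40, seed = 210))
  rec <- ds$records
  expect_equal(rec$lnsd_bc, log(rec$sd_pct) + 1 / (2 * rec$n - 1), tolerance = 1e-12)
  expect_equal(rec$weight, 2 * rec$n - 1)
  expect_equal(rec$log_mean, log(rec$mean_pct), tolerance = 1e-12)
  expect_true(all(rec$n >= 2))
  expect_true(all(table(rec$trial_id) >= 2))
})

test_that("recovery tables have finite Monte-Carlo errors even at 2 replicates", {
  cfg <- meta_sim_config(n_trials = 20, seed = 211)
  tab <- parameter_recovery(cfg, n_reps = 2, tau2_ci = FALSE)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$mcse)))
  expect_true(all(is.finite(tab$rmse)))
  expect_equal(tab$n_nonconverged, rep(0L, 3))
  expect_error(parameter_recovery(cfg, n_reps = 1), "at least 2")
})
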