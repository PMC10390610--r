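test_that("the REML fitter agrees with dense-matrix and lme4 oracles", {
  ds <- small_fixture()
  fit <- fit_base_model(ds)
  X <- design_matrix_of(ds)
  rec <- ds$records

  oracle <- reml_direct_oracle(rec$lnsd_bc, X, rec$trial_id, rec$weight)
  expect_equal(unname(coef(fit)), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-5)
  expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4 * max(fit$tau2, fit$sigma2))

  skip_if_not_installed("lme4")
  m <- lme4::lmer(lnsd_bc ~ treatment + log_mean + (1 | trial_id), data = rec,
                  weights = weight, REML = TRUE,
                  control = lme4::lmerControl(optCtrl = list(xtol_abs = 1e-12,
                                                             ftol_abs = 1e-12)))
  expect_equal(unname(coef(fit)), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(fit$sigma2, sigma(m)^2, tolerance = 1e-6)
  expect_equal(fit$tau2, unname(lme4::VarCorr(m)$trial_id[1]),
               tolerance = 1e-5 * max(1, fit$tau2))
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-8)
})

test_that("ML estimation is available and agrees with the dense oracle", {
  ds <- medium_dataset(seed = 21, n_trials = 15)
  fit <- fit_base_model(ds, method = "ML", tau2_ci = FALSE)
  X <- design_matrix_of(ds)
  rec <- ds$records
  oracle <- reml_direct_oracle(rec$lnsd_bc, X, rec$trial_id, rec$weight, reml = FALSE)
  expect_equal(unname(coef(fit)), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-3 * max(1, fit$tau2))
})

test_that("with tau2 = 0 data the fit reduces to weighted least squares", {
  cfg <- meta_sim_config(n_trials = 120, tau2 = 0, seed = 31)
  ds <- simulate_meta_dataset(cfg)
  fit <- fit_base_model(ds, tau2_ci = FALSE)
  wls <- lm(lnsd_bc ~ treatment + log_mean, data = ds$records,
            weights = ds$records$weight)
  expect_lt(fit$tau2, 1e-4)
  expect_equal(unname(coef(fit)), unname(coef(wls)), tolerance = 1e-3)

  # exact identity when the ratio is pinned at zero by construction
  expect_equal(unname(.lmm_parts(.lmm_prep(ds$records$lnsd_bc,
                                           design_matrix_of(ds),
                                           ds$records$trial_id,
                                           ds$records$weight), 0)$beta),
               unname(coef(wls)), tolerance = 1e-10)
})

test_that("rescaling all weights leaves beta unchanged and rescales sigma2", {
  ds <- medium_dataset(seed = 41, n_trials = 40)
  fit1 <- fit_base_model(ds, tau2_ci = FALSE)
  rec2 <- ds$records
  rec2$weight <- rec2$weight * 7
  fit2 <- fit_base_model(meta_dataset(rec2, "raw"), tau2_ci = FALSE)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
  expect_equal(fit2$sigma2, 7 * fit1$sigma2, tolerance = 1e-4)
  expect_equal(fit2$tau2, fit1$tau2, tolerance = 1e-4 * max(1, fit1$tau2))
})

test_that("inflating every verum SD by exp(delta) shifts the treatment effect by delta", {
  cfg <- meta_sim_config(n_trials = 150, beta_t = 0, seed = 51)
  ds <- simulate_meta_dataset(cfg)
  fit0 <- fit_base_model(ds, tau2_ci = FALSE)
  delta <- 0.25
  rec <- ds$records
  iv <- rec$treatment == "verum"
  rec$sd_pct[iv] <- rec$sd_pct[iv] * exp(delta)
  rec$lnsd_bc[iv] <- rec$lnsd_bc[iv] + delta
  fit1 <- fit_base_model(meta_dataset(rec, "raw"), tau2_ci = FALSE)
  expect_equal(unname(coef(fit1)["treatment_verum"] - coef(fit0)["treatment_verum"]),
               delta, tolerance = 1e-8)
})

test_that("interaction results obey slope_verum - slope_placebo = slope_difference", {
  cfg <- meta_sim_config(n_trials = 60, seed = 61,
                         interaction_betas = c(disease_duration_years = 0.011))
  ds <- simulate_meta_dataset(cfg)
  ir <- fit_interaction_model(ds, "disease_duration_years", tau2_ci = FALSE)
  expect_equal(unname(ir$slope_verum["estimate"] - ir$slope_placebo["estimate"]),
               unname(ir$slope_difference["estimate"]), tolerance = 1e-12)
  expect_lt(ir$slope_difference["ci_low"], ir$slope_difference["ci_high"])
  expect_equal(ir$n_missing_arms, 0)
})

test_that("a generated interaction is recovered and a null one is not invented", {
  gen <- c(disease_duration_years = 0.011)
  est <- replicate(30, NA_real_)
  cover0 <- logical(30)
  for (r in 1:30) {
    cfg <- meta_sim_config(n_trials = 100, seed = 7000 + r, interaction_betas = gen)
    ir <- fit_interaction_model(simulate_meta_dataset(cfg),
                                "disease_duration_years", tau2_ci = FALSE)
    est[r] <- ir$slope_difference["estimate"]
    cfg0 <- meta_sim_config(n_trials = 100, seed = 8000 + r)
    ir0 <- fit_interaction_model(simulate_meta_dataset(cfg0),
                                 "disease_duration_years", tau2_ci = FALSE)
    cover0[r] <- ir0$slope_difference["ci_low"] <= 0 &&
      0 <= ir0$slope_difference["ci_high"]
  }
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.011), 4 * mcse)
  expect_gte(mean(cover0), 0.8)
})

test_that("missing-predictor arms are dropped and accounted for", {
  cfg <- meta_sim_config(n_trials = 80, seed = 71,
                         covariate_missing = c(disease_duration_years = 0.2))
  ds <- simulate_meta_dataset(cfg)
  ir <- fit_interaction_model(ds, "disease_duration_years", tau2_ci = FALSE)
  n_na <- sum(is.na(ds$records$disease_duration_years))
  expect_equal(ir$n_missing_arms, n_na)
  expect_equal(ir$fit$n_arms_used + n_na, ds$n_arms)
  rec_allna <- ds$records
  rec_allna$disease_duration_years <- NA_real_
  expect_error(fit_interaction_model(meta_dataset(rec_allna, "raw"),
                                     "disease_duration_years"), "every arm")
})

test_that("collapsing all drug classes to one level reproduces the base model", {
  ds <- medium_dataset(seed = 81, n_trials = 50)
  rec <- ds$records
  rec$drug_class <- ifelse(rec$treatment == "placebo", "placebo", "other")
  ds1 <- meta_dataset(rec, "raw")
  dc <- fit_drugclass_model(ds1, tau2_ci = FALSE)
  base <- fit_base_model(ds1, tau2_ci = FALSE)
  expect_equal(nrow(dc$contrasts), 1)
  expect_equal(dc$contrasts$estimate, unname(coef(base)["treatment_verum"]),
               tolerance = 1e-10)
  expect_equal(dc$contrasts$se, unname(base$se["treatment_verum"]), tolerance = 1e-8)
})

test_that("class-specific SD inflation elevates only that class's contrast", {
  cfg <- meta_sim_config(n_trials = 150, beta_t = 0, seed = 91)
  ds <- simulate_meta_dataset(cfg)
  rec <- ds$records
  target <- rec$drug_class == "GLP-1 receptor agonists"
  rec$lnsd_bc[target] <- rec$lnsd_bc[target] + 0.3
  rec$sd_pct[target] <- rec$sd_pct[target] * exp(0.3)
  dc <- fit_drugclass_model(meta_dataset(rec, "raw"), tau2_ci = FALSE)
  con <- dc$contrasts
  glp <- con[con$drug_class == "GLP-1 receptor agonists", ]
  others <- con[con$drug_class != "GLP-1 receptor agonists" & !con$unstable, ]
  expect_gt(glp$estimate, 0.2)
  expect_true(all(abs(others$estimate) < 0.15))
})

test_that("subgroup restriction keeps the class's verum arms plus their placebos", {
  ds <- medium_dataset(seed = 101, n_trials = 120)
  cls <- "GLP-1 receptor agonists"
  ir <- fit_subgroup(ds, cls, "baseline_hba1c_pct", tau2_ci = FALSE)
  trials <- unique(ds$records$trial_id[ds$records$drug_class == cls])
  expected_arms <- sum(ds$records$trial_id %in% trials &
                         (ds$records$drug_class == cls |
                            ds$records$treatment == "placebo"))
  expect_equal(ir$fit$n_arms_used, expected_arms)
  expect_error(fit_subgroup(ds, "no such class", "bmi"), "no trials")

  # when every retained trial carries the class, the subgroup is the whole set
  rec1 <- ds$records[ds$records$trial_id %in% trials &
                       ds$records$drug_class %in% c("placebo", cls), ]
  ds1 <- meta_dataset(rec1, "raw")
  ir1 <- fit_subgroup(ds1, cls, "baseline_hba1c_pct", tau2_ci = FALSE)
  expect_equal(ir1$fit$n_arms_used, nrow(rec1))
})

test_that("rank-deficient designs are rejected with the offending terms named", {
  ds <- small_fixture()
  rec <- ds$records
  rec$dup <- rec$log_mean
  expect_error(fit_weighted_lmm(meta_dataset(rec, "raw"),
                                ~ treatment + log_mean + dup),
               "rank deficient.*dup")
})

test_that("the profile interval for tau2 brackets the estimate and scales sanely", {
  ds <- medium_dataset(seed = 111, n_trials = 80)
  fit <- fit_base_model(ds)
  expect_lt(fit$tau2_ci[1], fit$tau2)
  expect_gt(fit$tau2_ci[2], fit$tau2)
  expect_gte(fit$tau2_ci[1], 0)
  # deviance at the bounds sits at the chi-square cutoff
  prep <- .lmm_prep(ds$records$lnsd_bc, design_matrix_of(ds),
                    ds$records$trial_id, ds$records$weight)
  dev_hat <- .lmm_dev(prep, fit$tau2, fit$sigma2)
  for (b in fit$tau2_ci) {
    dev_b <- .lmm_profile_dev(prep, b, TRUE, log(fit$sigma2))
    expect_equal(dev_b - dev_hat, qchisq(0.95, 1), tolerance = 1e-4)
  }
})

test_that("variance of arm means matches a brute-force two-pass variance", {
  ds <- medium_dataset(seed = 121, n_trials = 40)
  vom <- variance_of_means(ds)
  for (grp in c("verum", "placebo")) {
    x <- ds$records$mean_pct[ds$records$treatment == grp]
    two_pass <- sum((x - mean(x))^2) / (length(x) - 1)
    expect_equal(vom$variance[vom$treatment == grp], two_pass, tolerance = 1e-12)
    expect_lt(vom$ci_low[vom$treatment == grp], two_pass)
    expect_gt(vom$ci_high[vom$treatment == grp], two_pass)
  }
  rec_eq <- ds$records
  rec_eq$mean_pct <- 7.5
  expect_equal(variance_of_means(meta_dataset(rec_eq, "raw"))$variance, c(0, 0))
})

test_that("fits demand at least two complete trials", {
  ds <- small_fixture()
  rec <- ds$records[ds$records$trial_id == "t1", ]
  expect_error(fit_base_model(meta_dataset(rec, "raw")), "at least 2 trials")
})
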