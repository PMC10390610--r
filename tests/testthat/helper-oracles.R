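# Independent oracles used across the suite. Both deliberately avoid the
# package's computational path: dense per-trial covariance matrices, generic
# 2-parameter optimisation, no Woodbury identities, no profiling of beta.

# Direct numerical maximisation of the closed-form (restricted) likelihood
# of y = X beta + u_trial + e, u ~ N(0, tau2), e ~ N(0, sigma2 / w).
reml_direct_oracle <- function(y, X, trial, w, reml = TRUE) {
  trial <- as.factor(trial)
  idx <- split(seq_along(y), trial)
  neg2ll <- function(par) {
    s2 <- exp(par[1]); t2 <- exp(par[2])
    XtVinvX <- matrix(0, ncol(X), ncol(X))
    XtVinvy <- numeric(ncol(X))
    logdetV <- 0
    Vinv_list <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[[k]]
      V <- diag(s2 / w[i], length(i)) + t2
      Vinv_list[[k]] <- solve(V)
      logdetV <- logdetV + determinant(V, logarithm = TRUE)$modulus
      XtVinvX <- XtVinvX + t(X[i, , drop = FALSE]) %*% Vinv_list[[k]] %*% X[i, , drop = FALSE]
      XtVinvy <- XtVinvy + t(X[i, , drop = FALSE]) %*% Vinv_list[[k]] %*% y[i]
    }
    beta <- solve(XtVinvX, XtVinvy)
    quad <- 0
    for (k in seq_along(idx)) {
      i <- idx[[k]]
      r <- y[i] - X[i, , drop = FALSE] %*% beta
      quad <- quad + drop(t(r) %*% Vinv_list[[k]] %*% r)
    }
    val <- logdetV + quad
    if (reml) val <- val + determinant(XtVinvX, logarithm = TRUE)$modulus
    as.numeric(val)
  }
  best <- NULL
  for (start in list(c(0, 0), c(-2, -2), c(1, -4))) {
    o <- stats::optim(start, neg2ll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  s2 <- exp(best$par[1]); t2 <- exp(best$par[2])
  XtVinvX <- matrix(0, ncol(X), ncol(X)); XtVinvy <- numeric(ncol(X))
  for (i in idx) {
    Vinv <- solve(diag(s2 / w[i], length(i)) + t2)
    XtVinvX <- XtVinvX + t(X[i, , drop = FALSE]) %*% Vinv %*% X[i, , drop = FALSE]
    XtVinvy <- XtVinvy + t(X[i, , drop = FALSE]) %*% Vinv %*% y[i]
  }
  list(beta = drop(solve(XtVinvX, XtVinvy)), sigma2 = s2, tau2 = t2,
       vcov = solve(XtVinvX))
}

# Fixed 3-trial / 6-arm dataset with both treatment levels per trial.
small_fixture <- function() {
  reports <- data.frame(
    trial_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    arm_id = paste0("a", 1:6),
    treatment = rep(c("placebo", "verum"), 3),
    drug_class = rep(c("placebo", "DPP-4 inhibitors"), 3),
    n = c(40, 42, 100, 95, 30, 33),
    unit = "percent",
    mean = c(8.1, 7.4, 7.9, 7.2, 8.4, 7.8),
    sd = c(1.2, 1.3, 0.9, 1.0, 1.4, 1.5),
    age_years = c(57, 57, 55, 55, 60, 60),
    baseline_hba1c_pct = c(8.3, 8.3, 8.1, 8.1, 8.6, 8.6),
    track = "raw",
    stringsAsFactors = FALSE)
  meta_dataset(make_arm_record(reports), track = "raw")
}

# Larger fixed synthetic dataset for model behaviour tests.
medium_dataset <- function(seed = 11, n_trials = 60, beta_t = 0.037) {
  cfg <- meta_sim_config(n_trials = n_trials, beta_t = beta_t, seed = seed)
  simulate_meta_dataset(cfg)
}

design_matrix_of <- function(dataset, fixed = ~ treatment + log_mean) {
  rec <- dataset$records
  rec$treatment <- factor(rec$treatment, levels = c("placebo", "verum"))
  stats::model.matrix(fixed, rec)
}
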