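# Weighted random-intercept meta-regression engine.
#
# Model, per trial j and arm a:
#   y_ja = x_ja' beta + u_j + e_ja,  u_j ~ N(0, tau2),  e_ja ~ N(0, sigma2 / w_ja)
# with y the bias-corrected log(SD) and w = 2n - 1 the inverse variance of
# the bias-corrected estimate. The covariance of a trial's arms is
# sigma2 * Omega_j with Omega_j = diag(1/w) + theta * 11', theta = tau2/sigma2.
# beta and sigma2 are profiled out in closed form; the criterion is
# optimised over theta only, using Woodbury identities per trial block:
#   Omega_j^{-1} = W_j - theta (W_j 1)(1' W_j) / (1 + theta s_j),  s_j = sum w
#   log det Omega_j = -sum log w + log(1 + theta s_j)

.lmm_prep <- function(y, X, trial, w) {
  trial <- factor(trial)
  list(y = y, X = X, w = w, trial = trial,
       n = length(y), p = ncol(X),
       XtWX = crossprod(X * sqrt(w)),
       Xtwy = drop(crossprod(X, w * y)),
       T = rowsum(X * w, trial),
       g = drop(rowsum(w * y, trial)),
       s = drop(rowsum(w, trial)),
       ywy = sum(w * y^2),
       sumlogw = sum(log(w)))
}

# Profiled pieces at a given variance ratio theta; NULL when the profiled
# system is numerically singular in that region.
.lmm_parts <- function(prep, theta) {
  lam <- theta / (1 + theta * prep$s)
  A <- prep$XtWX - crossprod(prep$T * sqrt(lam))
  b <- prep$Xtwy - drop(crossprod(prep$T, lam * prep$g))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  # quadratic form via explicit residuals: r' Omega^-1 r suffers far less
  # cancellation than y' Omega^-1 y - b' beta on flat likelihood surfaces
  r <- prep$y - drop(prep$X %*% beta)
  gr <- drop(rowsum(prep$w * r, prep$trial))
  quad <- sum(prep$w * r^2) - sum(lam * gr^2)
  if (!is.finite(quad) || quad <= 0) return(NULL)
  list(beta = beta, chol = ch, quad = quad,
       logdetA = 2 * sum(log(diag(ch))),
       logdetOmega = -prep$sumlogw + sum(log1p(theta * prep$s)))
}

# -2 x profiled (restricted) log-likelihood, constants dropped.
.lmm_crit <- function(prep, theta, reml = TRUE) {
  parts <- .lmm_parts(prep, theta)
  if (is.null(parts)) return(Inf)
  df <- if (reml) prep$n - prep$p else prep$n
  crit <- df * log(parts$quad) + parts$logdetOmega
  if (reml) crit <- crit + parts$logdetA
  crit
}

# Deviance (-2 log-lik incl. data-dependent constants) at explicit (tau2,
# sigma2); used for the profile-likelihood interval for tau2.
.lmm_dev <- function(prep, tau2, sigma2, reml = TRUE) {
  parts <- .lmm_parts(prep, tau2 / sigma2)
  if (is.null(parts)) return(Inf)
  df <- if (reml) prep$n - prep$p else prep$n
  dev <- df * log(sigma2) + parts$logdetOmega + parts$quad / sigma2
  if (reml) dev <- dev + parts$logdetA
  dev
}

.lmm_profile_dev <- function(prep, tau2, reml = TRUE, ls2_centre = 0) {
  opt <- stats::optimize(function(ls2) .lmm_dev(prep, tau2, exp(ls2), reml),
                         interval = ls2_centre + c(-12, 12), tol = 1e-9)
  opt$objective
}

.lmm_tau2_ci <- function(prep, tau2_hat, sigma2_hat, reml, ci_level) {
  ls2c <- log(sigma2_hat)
  dev_min <- .lmm_dev(prep, tau2_hat, sigma2_hat, reml)
  cut <- dev_min + stats::qchisq(ci_level, 1)
  h <- function(t) .lmm_profile_dev(prep, t, reml, ls2c) - cut
  lo <- if (tau2_hat <= 1e-12 || h(tau2_hat * 1e-6) < 0) {
    0
  } else {
    stats::uniroot(h, c(tau2_hat * 1e-6, tau2_hat), tol = 1e-10)$root
  }
  hi0 <- max(tau2_hat, sigma2_hat * 1e-4)
  hi <- hi0 * 2
  while (h(hi) < 0 && hi < hi0 * 1e8) hi <- hi * 4
  up <- if (h(hi) < 0) Inf else stats::uniroot(h, c(max(tau2_hat, 1e-12), hi), tol = 1e-10)$root
  c(lo, up)
}

#' Fit the weighted random-intercept meta-regression model
#'
#' Fits, by restricted maximum likelihood (default) or maximum likelihood,
#' the arm-based model `lnsd_bc = X beta + u_trial + e`, with
#' `u_trial ~ N(0, tau2)` and residual variance `sigma2 / weight` per arm.
#' beta and sigma2 are profiled out analytically and the criterion is
#' maximised over the variance ratio on a log scale (three overlapping
#' restart intervals plus an explicit boundary check at tau2 = 0).
#'
#' @param dataset A [meta_dataset()].
#' @param fixed One-sided formula for the fixed effects, evaluated in the
#'   record table; the response is always the bias-corrected log(SD)
#'   `lnsd_bc`. Default `~ treatment + log_mean`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param ci_level Confidence level for Wald intervals (default 0.95).
#' @param tau2_ci Compute a profile-likelihood interval for `tau2`
#'   (default TRUE; set FALSE to skip the extra profiling in large
#'   simulation loops).
#' @return An object of class `lnsd_fit` with coefficients, model-based
#'   standard errors, Wald confidence intervals (normal quantiles),
#'   variance components `tau2` (trial intercepts, profile CI) and `sigma2`
#'   (residual scale multiplying `1/weight`), the maximised log-likelihood,
#'   complete-case counts and a convergence flag.
#' @details Fixed-effect estimates are invariant to rescaling all weights
#'   by a constant; only `sigma2` absorbs the scale. Under the
#'   inverse-variance interpretation of the weights `sigma2` is expected
#'   near 1, which can be checked, not assumed, from the fit.
#' @export
fit_weighted_lmm <- function(dataset, fixed = ~ treatment + log_mean,
                             method = c("REML", "ML"), ci_level = 0.95,
                             tau2_ci = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  method <- match.arg(method)
  reml <- method == "REML"
  rec <- dataset$records
  rec$treatment <- factor(rec$treatment, levels = c("placebo", "verum"))
  if ("drug_class" %in% all.vars(fixed)) {
    lev <- unique(rec$drug_class)
    rec$drug_class <- factor(rec$drug_class,
                             levels = c("placebo", sort(setdiff(lev, "placebo"))))
  }
  vars <- all.vars(fixed)
  need <- unique(c("lnsd_bc", "weight", "trial_id", vars))
  cc <- stats::complete.cases(rec[, need, drop = FALSE])
  sub <- rec[cc, , drop = FALSE]
  if (length(unique(sub$trial_id)) < 2) {
    stop("at least 2 trials with complete data are required", call. = FALSE)
  }
  X <- stats::model.matrix(fixed, sub)
  colnames(X) <- gsub("treatmentverum", "treatment_verum",
                      gsub("drug_class", "drug_class:", colnames(X)), fixed = FALSE)
  y <- sub$lnsd_bc
  w <- sub$weight

  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  prep <- .lmm_prep(y, X, sub$trial_id, w)
  f <- function(lt) .lmm_crit(prep, exp(lt), reml)
  # boundary + three fixed restart intervals on log(theta)
  cands <- list(list(theta = 0, crit = .lmm_crit(prep, 0, reml)))
  for (iv in list(c(-30, -5), c(-10, 5), c(-2, 15))) {
    o <- stats::optimize(f, interval = iv, tol = 1e-10)
    cands[[length(cands) + 1L]] <- list(theta = exp(o$minimum), crit = o$objective)
  }
  crits <- vapply(cands, `[[`, numeric(1), "crit")
  best <- cands[[which.min(crits)]]
  converged <- is.finite(best$crit)
  theta <- best$theta
  if (theta > 0) {
    # local polish: the restart grids leave the argmin only loosely located
    # when the criterion is nearly flat in log(theta)
    o <- stats::optimize(f, log(theta) + c(-0.1, 0.1), tol = 1e-12)
    if (o$objective <= best$crit) theta <- exp(o$minimum)
  }
  parts <- .lmm_parts(prep, theta)
  if (is.null(parts)) stop("variance profiling failed at the optimum", call. = FALSE)

  df <- if (reml) prep$n - prep$p else prep$n
  sigma2 <- parts$quad / df
  tau2 <- theta * sigma2
  Ainv <- chol2inv(parts$chol)
  V <- sigma2 * Ainv
  beta <- drop(parts$beta)
  names(beta) <- colnames(X)
  se <- sqrt(diag(V))
  z <- stats::qnorm((1 + ci_level) / 2)
  ci <- cbind(low = beta - z * se, high = beta + z * se)
  dimnames(V) <- list(colnames(X), colnames(X))
  names(se) <- colnames(X)
  loglik <- -0.5 * (df * log(sigma2) + parts$logdetOmega +
                      (if (reml) parts$logdetA else 0) + df + df * log(2 * pi))
  t2ci <- if (tau2_ci) .lmm_tau2_ci(prep, tau2, sigma2, reml, ci_level) else c(NA_real_, NA_real_)

  structure(list(coefficients = beta, se = se, ci = ci, vcov = V,
                 tau2 = tau2, tau2_ci = t2ci, sigma2 = sigma2,
                 theta = theta, loglik = loglik, method = method,
                 ci_level = ci_level, fixed = fixed,
                 n_arms_used = prep$n,
                 n_trials_used = length(unique(sub$trial_id)),
                 n_arms_dropped = sum(!cc),
                 converged = converged),
            class = "lnsd_fit")
}

#' @export
print.lnsd_fit <- function(x, digits = 4, ...) {
  cat("Weighted random-intercept meta-regression (", x$method, ")\n", sep = "")
  cat("  ", x$n_arms_used, " arms, ", x$n_trials_used, " trials",
      if (x$n_arms_dropped > 0) paste0(" (", x$n_arms_dropped, " arms dropped, incomplete)"),
      "\n\n", sep = "")
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(tab, digits))
  cat(sprintf("\ntau2 (trial intercepts): %.*f", digits, x$tau2))
  if (!any(is.na(x$tau2_ci))) {
    cat(sprintf(" (%d%% profile CI: %.*f, %.*f)", round(100 * x$ci_level),
                digits, x$tau2_ci[1], digits, x$tau2_ci[2]))
  }
  cat(sprintf("\nsigma2 (residual scale):  %.*f\n", digits, x$sigma2))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
coef.lnsd_fit <- function(object, ...) object$coefficients

#' @export
vcov.lnsd_fit <- function(object, ...) object$vcov

#' @export
logLik.lnsd_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2, class = "logLik")
}

#' Fit the base treatment-heterogeneity model
#'
#' Fixed effects: intercept, treatment (verum vs placebo) and the log mean
#' HbA1c after treatment; random intercept per trial; weights `2n - 1`. The
#' treatment coefficient estimates the verum minus placebo difference in
#' log(SD): values above 0 indicate larger outcome variability under active
#' treatment, i.e. treatment heterogeneity.
#'
#' @inheritParams fit_weighted_lmm
#' @return An `lnsd_fit`; the treatment contrast is
#'   `coef(fit)["treatment_verum"]`.
#' @export
fit_base_model <- function(dataset, method = "REML", ci_level = 0.95,
                           tau2_ci = TRUE) {
  fit_weighted_lmm(dataset, ~ treatment + log_mean, method = method,
                   ci_level = ci_level, tau2_ci = tau2_ci)
}

#' Fit a treatment-by-predictor interaction model
#'
#' Extends the base model with a predictor main effect and its interaction
#' with treatment. Reported are the adjusted predictor slopes within the
#' placebo arms, within the verum arms, and their difference (the
#' interaction coefficient itself), each with Wald confidence intervals
#' from the fitted coefficient covariance. Predictors are kept on their
#' reporting scale (years, %, kg/m2, weeks, calendar year); no centering.
#'
#' @inheritParams fit_weighted_lmm
#' @param predictor Name of a covariate column in the records.
#' @return An object of class `lnsd_interaction` with `slope_placebo`,
#'   `slope_verum`, `slope_difference` (each `estimate`, `ci_low`,
#'   `ci_high`), `n_missing_arms`, and the underlying `fit`.
#' @export
fit_interaction_model <- function(dataset, predictor, method = "REML",
                                  ci_level = 0.95, tau2_ci = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rec <- dataset$records
  if (!predictor %in% names(rec)) stop("unknown predictor: ", predictor, call. = FALSE)
  if (all(is.na(rec[[predictor]]))) {
    stop("predictor '", predictor, "' is missing on every arm", call. = FALSE)
  }
  fixed <- stats::reformulate(c("treatment", "log_mean", predictor,
                                paste0("treatment:", predictor)))
  fit <- fit_weighted_lmm(dataset, fixed, method = method, ci_level = ci_level,
                          tau2_ci = tau2_ci)
  cn <- names(coef(fit))
  i_p <- which(cn == predictor)
  i_int <- grep(":", cn)
  if (length(i_p) != 1 || length(i_int) != 1) {
    stop("could not locate predictor and interaction terms in the fit", call. = FALSE)
  }
  b <- coef(fit)
  V <- vcov(fit)
  z <- stats::qnorm((1 + ci_level) / 2)
  mk <- function(est, var) {
    est <- unname(est)
    se <- sqrt(unname(var))
    c(estimate = est, ci_low = est - z * se, ci_high = est + z * se)
  }
  base_cc <- stats::complete.cases(rec[, c("lnsd_bc", "weight", "trial_id",
                                           "treatment", "log_mean")])
  structure(list(
    predictor = predictor,
    slope_placebo = mk(b[i_p], V[i_p, i_p]),
    slope_verum = mk(b[i_p] + b[i_int],
                     V[i_p, i_p] + V[i_int, i_int] + 2 * V[i_p, i_int]),
    slope_difference = mk(b[i_int], V[i_int, i_int]),
    n_missing_arms = sum(is.na(rec[[predictor]][base_cc])),
    fit = fit), class = "lnsd_interaction")
}

#' @export
print.lnsd_interaction <- function(x, digits = 4, ...) {
  fmt <- function(s) sprintf("%.*f (%.*f, %.*f)", digits, s[1], digits, s[2], digits, s[3])
  cat("Treatment-by-predictor interaction:", x$predictor, "\n")
  cat("  slope in verum arms:   ", fmt(x$slope_verum), "\n")
  cat("  slope in placebo arms: ", fmt(x$slope_placebo), "\n")
  cat("  difference (verum-placebo):", fmt(x$slope_difference), "\n")
  cat("  arms missing the predictor:", x$n_missing_arms, "\n")
  invisible(x)
}

#' Fit the drug-class model
#'
#' Replaces the binary treatment term with a drug-class factor (placebo as
#' reference), keeping the log-mean adjustment, the trial random intercept
#' and the inverse-variance weights. Each class coefficient is that class's
#' verum minus placebo difference in log(SD).
#'
#' @inheritParams fit_weighted_lmm
#' @return An object of class `lnsd_contrasts`: data frame `contrasts`
#'   (class, estimate, se, ci bounds, n_arms, `unstable` flag for classes
#'   with fewer than 2 arms) plus the underlying `fit`.
#' @export
fit_drugclass_model <- function(dataset, method = "REML", ci_level = 0.95,
                                tau2_ci = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rec <- dataset$records
  classes <- setdiff(unique(rec$drug_class), "placebo")
  if (length(classes) < 1 || !any(rec$drug_class == "placebo")) {
    stop("drug-class model needs placebo arms and at least one verum class",
         call. = FALSE)
  }
  fit <- fit_weighted_lmm(dataset, ~ drug_class + log_mean, method = method,
                          ci_level = ci_level, tau2_ci = tau2_ci)
  cn <- names(coef(fit))
  idx <- grep("^drug_class:", cn)
  cls <- sub("^drug_class:", "", cn[idx])
  n_arms <- vapply(cls, function(k) sum(rec$drug_class == k), integer(1))
  contrasts <- data.frame(
    drug_class = cls,
    estimate = unname(coef(fit)[idx]),
    se = unname(fit$se[idx]),
    ci_low = unname(fit$ci[idx, "low"]),
    ci_high = unname(fit$ci[idx, "high"]),
    n_arms = unname(n_arms),
    unstable = unname(n_arms) < 2,
    stringsAsFactors = FALSE)
  structure(list(contrasts = contrasts, fit = fit), class = "lnsd_contrasts")
}

#' @export
print.lnsd_contrasts <- function(x, digits = 3, ...) {
  cat("Drug-class differences in log(SD) vs placebo\n")
  df <- x$contrasts
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-30s %.*f (%.*f, %.*f)  [%d arms]%s\n", df$drug_class[i],
                digits, df$estimate[i], digits, df$ci_low[i], digits, df$ci_high[i],
                df$n_arms[i], if (df$unstable[i]) "  UNSTABLE" else ""))
  }
  invisible(x)
}

#' Interaction analysis within a drug-class subgroup
#'
#' Restricts the dataset to trials containing at least one arm of the given
#' class, keeping that class's verum arms together with the placebo arms of
#' those trials, then runs [fit_interaction_model()].
#'
#' @inheritParams fit_interaction_model
#' @param drug_class Class label, e.g. `"GLP-1 receptor agonists"`.
#' @return An `lnsd_interaction` for the subgroup.
#' @export
fit_subgroup <- function(dataset, drug_class, predictor, method = "REML",
                         ci_level = 0.95, tau2_ci = TRUE) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rec <- dataset$records
  trials <- unique(rec$trial_id[rec$drug_class == drug_class])
  if (length(trials) == 0) stop("no trials contain drug class '", drug_class, "'",
                                call. = FALSE)
  keep <- rec$trial_id %in% trials &
    (rec$drug_class == drug_class | rec$treatment == "placebo")
  sub <- meta_dataset(rec[keep, , drop = FALSE], track = dataset$track)
  fit_interaction_model(sub, predictor, method = method, ci_level = ci_level,
                        tau2_ci = tau2_ci)
}

#' Variance of arm means by treatment group (corridor-effect check)
#'
#' A treatment that steers everyone into a narrow glycaemic corridor
#' compresses the spread of arm-level mean outcomes; comparing the variance
#' of mean HbA1c across verum vs placebo arms probes this. Confidence
#' intervals are the chi-square intervals for a normal variance.
#'
#' @inheritParams fit_weighted_lmm
#' @return Data frame with one row per treatment group: `n_arms`,
#'   `variance`, `ci_low`, `ci_high`.
#' @export
variance_of_means <- function(dataset, ci_level = 0.95) {
  stopifnot(inherits(dataset, "meta_dataset"))
  rec <- dataset$records
  out <- lapply(c("verum", "placebo"), function(grp) {
    x <- rec$mean_pct[rec$treatment == grp]
    x <- x[!is.na(x)]
    k <- length(x)
    if (k < 2) stop("fewer than 2 ", grp, " arms with a mean value", call. = FALSE)
    s2 <- stats::var(x)
    a <- (1 - ci_level) / 2
    data.frame(treatment = grp, n_arms = k, variance = s2,
               ci_low = (k - 1) * s2 / stats::qchisq(1 - a, k - 1),
               ci_high = (k - 1) * s2 / stats::qchisq(a, k - 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
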