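#' Linear mixed-effects model of longitudinal volume change
#'
#' Fits the slope-only random-effects model
#' `longVC_it = (beta1 + beta2 * Group + b_i) * t_it + eps_it`
#' by maximum likelihood (no intercept: longVC is 0 at baseline by
#' construction). Groups are coded NC = 0, AD = 1, so `beta1` is the normal
#' annual change of longVC (percent/yr) and `beta2` the additional change in
#' the AD group. An optional fixed intercept can be toggled on.
#'
#' @param table data frame with columns `subject`, `group` (NC / AD),
#'   `time` (years) and `longvc` (percent).
#' @param intercept include a fixed intercept (default FALSE, as the model
#'   passes through the origin).
#' @return an `lme_fit` object: fixed effects `beta1`, `beta2` and their
#'   standard errors, random-slope sd, residual sd, the average correlation
#'   of repeated observations, the per-visit common variance, and the
#'   underlying `lmerMod` in `$model`.
#' @export
fit_lme <- function(table, intercept = FALSE) {
  stopifnot(all(c("subject", "group", "time", "longvc") %in% names(table)))
  tab <- table
  tab$g <- as.numeric(tab$group == "AD")
  if (length(unique(tab$subject)) < 4)
    stop("fit_lme needs several subjects per group")
  form <- if (intercept)
    longvc ~ 1 + time + time:g + (0 + time | subject)
  else
    longvc ~ 0 + time + time:g + (0 + time | subject)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = tab, REML = FALSE)))
  fe <- lme4::fixef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
                 error = function(e) rep(NA_real_, length(fe)))
  if (length(se) != length(fe)) se <- rep(NA_real_, length(fe))
  vc <- as.data.frame(lme4::VarCorr(fit))
  slope_sd <- vc$sdcor[vc$grp == "subject"][1]
  resid_sd <- stats::sigma(fit)
  # common variance and average correlation of the repeated observations
  # implied by the random-slope covariance sigma_b^2 x_j x_k + sigma_e^2 d_jk
  tt <- sort(unique(tab$time))
  vjj <- slope_sd^2 * tt^2 + resid_sd^2
  sigma2 <- mean(vjj)
  pairs <- which(upper.tri(matrix(0, length(tt), length(tt))), arr.ind = TRUE)
  rho <- mean(slope_sd^2 * tt[pairs[, 1]] * tt[pairs[, 2]] /
                sqrt(vjj[pairs[, 1]] * vjj[pairs[, 2]]))
  structure(list(
    beta1 = unname(fe["time"]), beta2 = unname(fe["time:g"]),
    se_beta1 = unname(se[names(fe) == "time"]),
    se_beta2 = unname(se[names(fe) == "time:g"]),
    slope_sd = slope_sd, resid_sd = resid_sd,
    sigma2 = sigma2, rho = rho, times = tt,
    n_nc = length(unique(tab$subject[tab$g == 0])),
    n_ad = length(unique(tab$subject[tab$g == 1])),
    singular = lme4::isSingular(fit), intercept = intercept,
    model = fit), class = "lme_fit")
}

#' @exportS3Method print lme_fit
print.lme_fit <- function(x, ...) {
  cat(sprintf("<lme_fit> beta1 = %.3f (SE %.3f), beta2 = %.3f (SE %.3f) %%/yr\n",
              x$beta1, x$se_beta1, x$beta2, x$se_beta2))
  cat(sprintf("  slope sd %.3f, residual sd %.3f, rho %.3f; n = %d NC / %d AD%s\n",
              x$slope_sd, x$resid_sd, x$rho, x$n_nc, x$n_ad,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' @exportS3Method summary lme_fit
summary.lme_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying mixed model:\n")
  print(summary(object$model))
  invisible(object)
}

#' Sample size per arm for a rate-of-change trial (Diggle formula)
#'
#' Subjects per arm needed to detect a reduction of the AD-arm annual rate at
#' the given power:
#' `n = 2 (z_(1-alpha/2) + z_power)^2 sigma^2 (1 - rho) / (m s_x^2 d^2)`
#' with `sigma^2` the common variance of the repeated measures, `rho` their
#' correlation, `m` the number of visits, `s_x^2` the within-subject variance
#' of the visit times, and `d` the treatment effect on the rate (percent/yr).
#' The result is rounded up.
#'
#' @param fit an [fit_lme()] result (or a list providing `sigma2`, `rho`,
#'   `beta1`, `beta2`).
#' @param reduction fraction of the AD-arm rate the treatment removes
#'   (default 0.25).
#' @param power target power (default 0.80).
#' @param alpha two-sided type-I error (default 0.05).
#' @param visit_times visit times; defaults to the fit's.
#' @param effect absolute effect size d in percent/yr; overrides `reduction`.
#' @return a `power_result` list: `n_per_arm`, `effect`, `power`, `alpha`,
#'   and the formula inputs.
#' @export
sample_size <- function(fit, reduction = 0.25, power = 0.80, alpha = 0.05,
                        visit_times = NULL, effect = NULL) {
  tt <- if (is.null(visit_times)) fit$times else visit_times
  m <- length(tt)
  sx2 <- mean((tt - mean(tt))^2)
  if (is.null(effect)) {
    ad_rate <- fit$beta1 + fit$beta2
    effect <- reduction * abs(ad_rate)
  }
  if (abs(effect) < 1e-12) stop("sample_size: zero effect size")
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  n_raw <- 2 * z^2 * fit$sigma2 * (1 - fit$rho) / (m * sx2 * effect^2)
  structure(list(n_per_arm = ceiling(n_raw), n_raw = n_raw, effect = effect,
                 power = power, alpha = alpha, sigma2 = fit$sigma2,
                 rho = fit$rho, m = m, sx2 = sx2),
            class = "power_result")
}

#' @exportS3Method print power_result
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> n/arm = %d (effect %.3f %%/yr, power %.0f%%, alpha %.2f)\n",
              x$n_per_arm, x$effect, 100 * x$power, x$alpha))
  invisible(x)
}

#' Parametric bootstrap confidence intervals for the LME power analysis
#'
#' Simulates responses from the fitted mixed model, refits, and recomputes
#' the fixed effects and the Diggle sample size; percentile 2.5/97.5
#' intervals are returned. Reproducible under a fixed seed.
#'
#' @param fit an [fit_lme()] result.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param reduction,power,alpha forwarded to [sample_size()].
#' @return a list with `ci` (data frame of 2.5/97.5 percentiles for beta1,
#'   beta2 and n_per_arm), `replicates` (the bootstrap draws) and
#'   `n_failed`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1, reduction = 0.25,
                         power = 0.80, alpha = 0.05) {
  set.seed(seed %% 2147483647)
  sims <- simulate(fit$model, nsim = n_boot)
  dat <- fit$model@frame
  res <- matrix(NA_real_, n_boot, 3,
                dimnames = list(NULL, c("beta1", "beta2", "n_per_arm")))
  for (b in seq_len(n_boot)) {
    dat$longvc <- sims[[b]]
    bf <- tryCatch(
      suppressMessages(suppressWarnings(stats::update(fit$model, data = dat))),
      error = function(e) NULL)
    if (is.null(bf)) next
    fe <- lme4::fixef(bf)
    vc <- as.data.frame(lme4::VarCorr(bf))
    slope_sd <- vc$sdcor[vc$grp == "subject"][1]
    resid_sd <- stats::sigma(bf)
    tt <- fit$times
    vjj <- slope_sd^2 * tt^2 + resid_sd^2
    pairs <- which(upper.tri(diag(length(tt))), arr.ind = TRUE)
    sub <- list(sigma2 = mean(vjj),
                rho = mean(slope_sd^2 * tt[pairs[, 1]] * tt[pairs[, 2]] /
                             sqrt(vjj[pairs[, 1]] * vjj[pairs[, 2]])),
                beta1 = unname(fe["time"]), beta2 = unname(fe["time:g"]),
                times = tt)
    ss <- tryCatch(sample_size(sub, reduction = reduction, power = power,
                               alpha = alpha),
                   error = function(e) NULL)
    res[b, ] <- c(sub$beta1, sub$beta2,
                  if (is.null(ss)) NA_real_ else ss$n_per_arm)
  }
  n_failed <- sum(is.na(res[, "beta1"]))
  if (n_failed > 0.2 * n_boot)
    stop("bootstrap_ci: more than 20% of refits failed")
  ci <- t(apply(res, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
  list(ci = as.data.frame(ci), replicates = res, n_failed = n_failed)
}

#' Paired scan-rescan comparisons between two methods
#'
#' Two-sided paired t-test on the signed volume changes (bias) and two-sided
#' Wilcoxon signed-rank test on the absolute volume changes (variability);
#' the absolute changes are not normal, hence the rank test. All-zero
#' differences return p = 1 by convention.
#'
#' @param vc_a,vc_b paired VC vectors (method A vs B).
#' @param avc_a,avc_b paired aVC vectors; default `abs(vc)`.
#' @return list with `p_t_vc` and `p_wilcoxon_avc` (and the test objects).
#' @export
scan_rescan_tests <- function(vc_a, vc_b, avc_a = abs(vc_a),
                              avc_b = abs(vc_b)) {
  stopifnot(length(vc_a) == length(vc_b), length(avc_a) == length(avc_b))
  if (length(vc_a) < 5) warning("fewer than 5 pairs: tests are unreliable")
  safe <- function(expr) tryCatch(suppressWarnings(expr)$p.value,
                                  error = function(e) 1)
  p_t <- if (sd(vc_a - vc_b) < 1e-14) 1 else
    safe(t.test(vc_a, vc_b, paired = TRUE))
  dif <- avc_a - avc_b
  p_w <- if (all(abs(dif) < 1e-14)) 1 else
    safe(wilcox.test(avc_a, avc_b, paired = TRUE, exact = FALSE))
  list(p_t_vc = p_t, p_wilcoxon_avc = p_w)
}
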