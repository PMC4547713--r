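# Volume-change metrics, mixed models, power analysis.

test_that("structure_volume integrates the Jacobian determinant over masks", {
  g <- mk_grid(16, 1)        # 1 mm voxels
  mask <- g
  mask$data[4:13, 4:13, 4:13] <- 1    # 1000 voxels
  expect_equal(structure_volume(mask, zero_field(g)), 1000)
  w <- grid_world(g)
  s <- 0.97
  fs <- as_field(array((s - 1) * w, c(dim(g$data), 3)), g$affine)
  expect_equal(structure_volume(mask, fs), 1000 * s^3, tolerance = 1e-10)
  expect_error(structure_volume(g, zero_field(g)), "empty mask")
})

test_that("synthetic radial atrophy matches its voxel-count oracle", {
  spec <- test_spec()
  ph <- get_phantom()
  f <- atrophy_field(spec, "ventricles", t = 1, rate = -9)
  v <- structure_volume(ph$masks$ventricles, jacobian_determinant(f))
  v0 <- sum(ph$masks$ventricles$data) * spec$voxel_size^3
  expect_lt(abs(v / v0 - 1.09) / 1.09, 0.05)
})

test_that("VC, aVC and longVC follow their defining formulas", {
  expect_equal(vc_avc(c(100, 100, 100, 100))$VC, rep(0, 4))
  r <- vc_avc(c(90, 110))
  expect_equal(r$VC, c(10, -10))
  expect_equal(r$aVC, c(10, 10))
  # algebraic identity: sum of V_t (1 - VC_t/100)... mean-centering
  v <- c(93, 104, 99, 101)
  expect_equal(mean(vc_avc(v)$VC), 0, tolerance = 1e-12)
  expect_equal(long_vc(c(100, 100)), c(0, 0))
  expect_equal(long_vc(c(100, 95)), c(0, 5))
  expect_equal(long_vc(c(100, 110)), c(0, -10))
  # scale invariance
  expect_equal(vc_avc(3 * v)$VC, vc_avc(v)$VC)
  expect_equal(long_vc(3 * v), long_vc(v))
  expect_error(vc_avc(c(1, -2)), "positive")
})

mk_cohort_table <- function(n, b1 = 0.7, b2 = 1.2, slope_sd = 0.5,
                            eps_sd = 0.3, times = c(0, 0.5, 1, 2),
                            seed = 1) {
  set.seed(seed)
  tab <- expand.grid(subject = sprintf("S%03d", seq_len(2 * n)),
                     time = times)
  id <- as.integer(sub("S", "", tab$subject))
  tab$group <- ifelse(id <= n, "NC", "AD")
  b <- rnorm(2 * n, 0, slope_sd)[id]
  tab$longvc <- (b1 + b2 * (tab$group == "AD") + b) * tab$time +
    rnorm(nrow(tab), 0, eps_sd)
  tab
}

test_that("fit_lme recovers exact and simulated effects, and label swaps negate beta2", {
  tt <- c(0, 0.5, 1, 2)
  tab <- expand.grid(subject = sprintf("S%02d", 1:10), time = tt)
  tab$group <- ifelse(as.integer(sub("S", "", tab$subject)) <= 5, "NC", "AD")
  tab$longvc <- ifelse(tab$group == "NC", 1.0, 3.0) * tab$time
  fit <- fit_lme(tab)
  expect_equal(fit$beta1, 1, tolerance = 1e-6)
  expect_equal(fit$beta2, 2, tolerance = 1e-6)
  tab2 <- tab
  tab2$group <- ifelse(tab$group == "NC", "AD", "NC")
  fit2 <- fit_lme(tab2)
  expect_equal(fit2$beta2, -fit$beta2, tolerance = 1e-6)
  expect_equal(fit2$beta1 + fit2$beta2, fit$beta1, tolerance = 1e-6)
  # Monte-Carlo calibration: estimates within 2 SE in >= 95% of replicates
  hits1 <- hits2 <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    f <- fit_lme(mk_cohort_table(50, seed = r))
    hits1 <- hits1 + (abs(f$beta1 - 0.7) <= 2 * f$se_beta1)
    hits2 <- hits2 + (abs(f$beta2 - 1.2) <= 2 * f$se_beta2)
  }
  expect_gte(hits1 / reps, 0.9)
  expect_gte(hits2 / reps, 0.9)
})

test_that("fit_lme bias shrinks with sample size", {
  err <- vapply(c(20, 50, 100), function(n) {
    es <- vapply(1:10, function(r)
      fit_lme(mk_cohort_table(n, seed = 100 * n + r))$beta2 - 1.2, 0)
    abs(mean(es))
  }, 0)
  expect_lt(err[3], 0.15)
  expect_lt(err[3], err[1] + 0.1)
})

test_that("Diggle sample size matches hand evaluation and scaling laws", {
  tt <- c(0, 0.5, 1, 2)
  f <- list(sigma2 = 4, rho = 0.5, beta1 = 1, beta2 = 1, times = tt)
  ss <- sample_size(f, effect = 0.5)
  z <- qnorm(0.975) + qnorm(0.8)
  n_hand <- 2 * z^2 * 4 * (1 - 0.5) / (4 * mean((tt - mean(tt))^2) * 0.5^2)
  expect_equal(ss$n_raw, n_hand, tolerance = 1e-12)
  expect_equal(ss$n_per_arm, ceiling(n_hand))
  # d^-2 law exact before rounding
  expect_equal(ss$n_raw / sample_size(f, effect = 1)$n_raw, 4,
               tolerance = 1e-12)
  # monotonicity over a parameter grid
  expect_gt(sample_size(f, effect = 0.5, power = 0.9)$n_raw, ss$n_raw)
  for (s2 in c(2, 6)) for (rho in c(0.2, 0.8)) {
    fi <- f; fi$sigma2 <- s2; fi$rho <- rho
    ni <- sample_size(fi, effect = 0.5)$n_raw
    expect_equal(ni, n_hand * (s2 / 4) * (1 - rho) / 0.5, tolerance = 1e-12)
  }
  expect_error(sample_size(f, effect = 0), "zero effect")
})

test_that("parametric bootstrap is reproducible and nearly degenerate without noise", {
  fit <- fit_lme(mk_cohort_table(30, seed = 3))
  b1 <- bootstrap_ci(fit, n_boot = 40, seed = 7)
  b2 <- bootstrap_ci(fit, n_boot = 40, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci["beta2", 1] < fit$beta2 && fit$beta2 < b1$ci["beta2", 2])
  # near-zero noise: tight intervals
  fit0 <- fit_lme(mk_cohort_table(20, slope_sd = 1e-4, eps_sd = 1e-4,
                                  seed = 4))
  b0 <- bootstrap_ci(fit0, n_boot = 20, seed = 1)
  expect_lt(b0$ci["beta1", 2] - b0$ci["beta1", 1], 0.01)
})

test_that("bootstrap intervals cover the truth in a seeded calibration study", {
  reps <- 40
  cover <- 0
  for (r in seq_len(reps)) {
    fit <- fit_lme(mk_cohort_table(25, seed = 500 + r))
    ci <- bootstrap_ci(fit, n_boot = 60, seed = r)$ci
    cover <- cover + (ci["beta2", 1] <= 1.2 && 1.2 <= ci["beta2", 2])
  }
  expect_gte(cover / reps, 0.9)
})

test_that("scan-rescan paired tests behave on degenerate, shifted and null data", {
  s <- scan_rescan_tests(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(s$p_t_vc, 1)
  expect_equal(s$p_wilcoxon_avc, 1)
  set.seed(1)
  a <- rnorm(20)
  s2 <- scan_rescan_tests(a + 2, a + rnorm(20, 0, 0.01))
  expect_lt(s2$p_t_vc, 1e-6)
  # type-I error under exchangeable noise
  rej <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    set.seed(r)
    x <- rnorm(15); y <- rnorm(15)
    rej <- rej + (scan_rescan_tests(x, y)$p_t_vc < 0.05)
  }
  expect_gte(rej / reps, 0.02)
  expect_lte(rej / reps, 0.09)
})
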