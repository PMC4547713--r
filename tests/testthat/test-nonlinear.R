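# Non-linear registration, template iteration, longitudinal bias correction.

test_that("registering an image to itself produces a negligible field", {
  ph <- get_phantom(texture = TRUE)
  lvl <- list(step = 8, blur = 4, neighborhood = 24, iterations = 2)
  u <- register_nonlinear(ph$volume, ph$volume, lvl)
  expect_lt(max(abs(u$vectors)) / 2.5, 0.2)
})

test_that("a uniform translation is recovered where the image has structure", {
  ph <- get_phantom(texture = TRUE)
  clean <- ph$volume
  M <- diag(4); M[1, 4] <- 2
  moved <- resample(clean, as_affine(M), clean, order = 4)
  u <- NULL
  sch <- default_schedule(4)
  for (l in seq_len(nrow(sch)))
    u <- register_nonlinear(moved, clean, as.list(sch[l, ]), init = u)
  # mean recovered displacement in the informative interior: boundary band
  # plus textured tissue (the pull-back of a +2 mm shift is -2 mm)
  db <- longmdt:::lobe_d(grid_world(clean),
                         test_spec()$structures$brain$centers[1, ],
                         test_spec()$structures$brain$radii[1, ])
  band <- array(db > 0.5 & db < 1, dim(clean$data))
  expect_lt(abs(median(u$vectors[, , , 1][band]) + 2), 0.5)
})

test_that("local growth is recovered as a Jacobian-integrated volume change", {
  spec <- test_spec()
  ph <- get_phantom(texture = TRUE)
  f <- atrophy_field(spec, "ventricles", t = 2, rate = -9)
  fi <- invert_field(f)
  vis <- resample(ph$volume, fi, fi, order = 4)
  u <- NULL
  sch <- default_schedule(4)
  sch$iterations <- c(1, 2, 3)
  for (l in seq_len(nrow(sch)))
    u <- register_nonlinear(vis, ph$volume, as.list(sch[l, ]), init = u)
  vm <- ph$masks$ventricles
  ratio <- structure_volume(vm, jacobian_determinant(u)) /
    (sum(vm$data) * spec$voxel_size^3)
  expect_lt(abs(ratio - 1.18) / 0.18, 0.35)   # most of the growth recovered
  expect_gt(ratio, 1.10)
})

test_that("template iteration leaves identical visits unchanged with zero mean field", {
  ph <- get_phantom(texture = TRUE)
  series <- list(ph$volume, ph$volume, ph$volume, ph$volume)
  times <- c(0, 0.5, 1, 2)
  mdt <- build_nonlinear_template(series, times,
                                  schedule = default_schedule(8),
                                  iters_per_level = 2,
                                  st_regularize = FALSE,
                                  bias_correct = FALSE)
  expect_lt(max(vapply(mdt$fields, function(f) max(abs(f$vectors)), 0)) / 2.5,
            0.3)
  expect_lt(max(mdt$level_log$mean_disp_vox), 0.1)
})

test_that("the mean deformation is removed at every iteration (unbiasedness)", {
  spec <- test_spec(seed = 30)
  set.seed(30)
  ds <- simulate_scan_rescan(spec, n_subjects = 1, n_scans = 4)
  sub <- ds$subjects[[1]]
  cfg <- pipeline_config(iters_per_level = 2, denoise = FALSE)
  pre <- preprocess_series(sub$scans, ds$reference$volume, cfg)
  mdt <- build_nonlinear_template(pre$volumes, sub$times,
                                  schedule = default_schedule(8),
                                  iters_per_level = 2,
                                  st_regularize = TRUE, bias_correct = TRUE)
  expect_lt(max(mdt$level_log$mean_disp_vox), 0.1)
})

test_that("longitudinal bias correction shares a single-visit bias and normalizes", {
  ph <- get_phantom(texture = TRUE)
  clean <- ph$volume
  g <- grid_world(clean)
  bias <- array(exp(0.08 * sin(2 * pi * g[, 1] / 200) *
                      cos(2 * pi * g[, 2] / 150)), dim(clean$data))
  series <- list(as_volume(clean$data * bias, clean$affine),
                 clean, clean, clean)
  psi <- replicate(4, zero_field(clean), simplify = FALSE)
  bc <- longitudinal_bias_correct(series, clean, psi, series, fwhm = 60)
  # geometric mean of the returned fields is 1 voxel-wise
  gm <- Reduce(`+`, lapply(bc$bias, function(b) log(b$values))) / 4
  expect_lt(max(abs(gm)), 1e-3)
  # the biased visit's field follows the injected bias to the power 3/4
  fg <- clean$data > 10
  expect_gt(stats::cor(log(bc$bias[[1]]$values[fg]), log(bias[fg])), 0.9)
  # sharing pattern: the biased visit carries the field positively, the
  # other visits carry the -1/n complement (negatively correlated)
  expect_gt(stats::cor(log(bc$bias[[2]]$values[fg]), log(bias[fg])), -1)
  expect_lt(stats::cor(log(bc$bias[[2]]$values[fg]), log(bias[fg])), -0.5)
  # bias-free series: fields within 1 +/- 0.02
  bc0 <- longitudinal_bias_correct(list(clean, clean, clean, clean), clean,
                                   psi, list(clean, clean, clean, clean))
  for (b in bc0$bias) expect_lt(max(abs(b$values - 1)), 0.02)
})

test_that("time-point transforms are near-identity for t1 = t2 and transitive", {
  ph <- get_phantom()
  g <- ph$volume
  set.seed(9)
  fields <- lapply(1:3, function(i) smooth_random_field(g, amp = 0.3,
                                                        fwhm_vox = 3,
                                                        seed = 40 + i))
  mdt <- structure(list(fields = fields, times = c(0, 1, 2)),
                   class = "mdt_template")
  same <- timepoint_transform(mdt, 2, 2)
  core <- as.logical(get_core_mask(dim(g$data)[1], 4))
  expect_lt(max(abs(matrix(same$vectors, ncol = 3)[core, ])) / 2.5, 0.05)
  # transitivity: (1->2) o (2->3) ~ (1->3)
  t12 <- timepoint_transform(mdt, 1, 2)
  t23 <- timepoint_transform(mdt, 2, 3)
  t13 <- timepoint_transform(mdt, 1, 3)
  lhs <- compose(t12, t23)
  err <- max(abs(matrix(lhs$vectors - t13$vectors, ncol = 3)[core, ]))
  expect_lt(err / 2.5, 0.5)
  expect_error(timepoint_transform(mdt, 1, 9), "unknown visit")
})
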