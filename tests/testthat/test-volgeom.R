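# Core geometry: resampling, composition, inversion, Jacobians.

test_that("resample is exact for identity and analytic shifts", {
  ramp <- ramp_volume(16, 2)
  for (ord in c(1, 4)) {
    r0 <- resample(ramp, NULL, ramp, order = ord)
    expect_lt(max(abs(r0$data - ramp$data)), 1e-10)
  }
  M <- diag(4); M[1, 4] <- 2            # one-voxel shift along x
  r1 <- resample(ramp, as_affine(M), ramp, order = 1)
  expect_lt(max(abs(r1$data[2:15, , ] - ramp$data[3:16, , ])), 1e-10)
})

test_that("trilinear and cubic resampling agree on a smooth blob", {
  blob <- blob_volume(20, 2, sigma_mm = 12)
  f <- smooth_random_field(mk_grid(20, 2), amp = 0.8, seed = 3)
  r1 <- resample(blob, f, f, order = 1)
  r4 <- resample(blob, f, f, order = 4)
  # closed-form oracle: evaluate the Gaussian at the warped coordinates
  w <- grid_world(blob) + matrix(f$vectors, ncol = 3)
  oracle <- 100 * exp(-rowSums(w^2) / (2 * 144))
  core <- as.logical(get_core_mask(20))
  expect_lt(max(abs(r1$data[core] - oracle[core])), 1)       # 1% of amp
  expect_lt(max(abs(r4$data[core] - oracle[core])), 1)
  expect_lt(max(abs(r4$data[core] - r1$data[core])), 1)
})

test_that("compose adds uniform translations and matches analytic scalings", {
  g <- mk_grid(16, 2)
  f1 <- zero_field(g); f1$vectors[, , , 1] <- 3
  f2 <- zero_field(g); f2$vectors[, , , 2] <- -2
  fc <- compose(f1, f2)
  core <- as.logical(get_core_mask(16))
  m <- matrix(fc$vectors, ncol = 3)[core, ]
  expect_lt(max(abs(sweep(m, 2, c(3, -2, 0)))), 1e-10)
  expect_equal(compose(zero_field(g), f1)$vectors, f1$vectors)

  # two scalings about the same center compose to the product scaling
  w <- grid_world(g)
  mk_scale <- function(s) as_field(array((s - 1) * w, c(dim(g$data), 3)),
                                   g$affine)
  s1 <- 1.04; s2 <- 0.97
  fc <- compose(mk_scale(s2), mk_scale(s1))
  target <- (s1 * s2 - 1) * w
  err <- max(abs(matrix(fc$vectors, ncol = 3)[core, ] - target[core, ]))
  expect_lt(err / 2, 1e-3)              # within 1e-3 voxel in the interior
})

test_that("invert_field round-trips uniform and smooth fields", {
  g <- mk_grid(16, 2)
  expect_equal(invert_field(zero_field(g))$vectors, zero_field(g)$vectors)
  f <- zero_field(g); f$vectors[, , , 1] <- 3
  fi <- invert_field(f)
  core <- as.logical(get_core_mask(16))
  expect_lt(max(abs(matrix(fi$vectors, ncol = 3)[core, 1] + 3)), 0.05)
  # sinusoid of amplitude 0.5 voxel
  w <- grid_world(g)
  u <- array(0, c(dim(g$data), 3))
  u[, , , 1] <- array(1 * sin(2 * pi * w[, 2] / 32), dim(g$data))
  fs <- as_field(u, g$affine)
  fi <- invert_field(fs)
  expect_true(attr(fi, "converged"))
  rt <- compose(fs, fi)
  expect_lt(max(abs(matrix(rt$vectors, ncol = 3)[core, ])) / 2, 0.05)
})

test_that("mean_field averages voxel-wise and is linear", {
  g <- mk_grid(10, 2)
  set.seed(7)
  fs <- lapply(1:5, function(i) smooth_random_field(g, amp = 2, seed = i))
  mf <- mean_field(fs)
  brute <- Reduce(`+`, lapply(fs, `[[`, "vectors")) / 5
  expect_equal(mf$vectors, brute)
  expect_equal(mean_field(list(fs[[1]], fs[[1]]))$vectors, fs[[1]]$vectors)
  f1 <- fs[[1]]; f2 <- fs[[2]]
  fneg <- f2; fneg$vectors <- -f2$vectors
  sum0 <- mean_field(list(f2, fneg))
  expect_lt(max(abs(sum0$vectors)), 1e-12)
  sc <- lapply(fs, function(f) { f$vectors <- 3 * f$vectors; f })
  expect_equal(mean_field(sc)$vectors, 3 * mf$vectors)
  expect_error(mean_field(list()), "at least one")
})

test_that("jacobian matrices are exact for linear fields, O(h^2) for smooth", {
  g <- mk_grid(16, 2)
  w <- grid_world(g)
  A <- matrix(c(0.02, 0.01, 0, 0, 0.03, 0.005, 0.01, 0, 0.02), 3, 3,
              byrow = TRUE)
  fl <- as_field(array(t(A %*% t(w)), c(dim(g$data), 3)), g$affine)
  J <- jacobian_matrix(fl)
  core <- as.logical(get_core_mask(16))
  for (r in 1:3) for (c in 1:3)
    expect_lt(max(abs(J$matrices[core, r + 3 * (c - 1)] - A[r, c])), 1e-12)
  # uniform translation -> zero
  ft <- zero_field(g); ft$vectors[, , , 2] <- 5
  expect_lt(max(abs(jacobian_matrix(ft)$matrices)), 1e-12)
  # sinusoid: halving h divides the error by ~4
  err_at <- function(n) {
    gg <- mk_grid(n, 32 / n)
    ww <- grid_world(gg)
    u <- array(0, c(dim(gg$data), 3))
    u[, , , 1] <- array(sin(2 * pi * ww[, 1] / 40), dim(gg$data))
    JJ <- jacobian_matrix(as_field(u, gg$affine))
    truth <- (2 * pi / 40) * cos(2 * pi * ww[, 1] / 40)
    core <- as.logical(get_core_mask(n))
    max(abs(JJ$matrices[core, 1] - truth[core]))
  }
  e1 <- err_at(16); e2 <- err_at(32)
  expect_gt(e1 / e2, 3)   # second-order convergence
})

test_that("jacobian determinants match analytic values and brute force", {
  g <- mk_grid(16, 2)
  expect_equal(unique(as.numeric(jacobian_determinant(zero_field(g))$data)), 1)
  w <- grid_world(g)
  s <- 0.97
  fs <- as_field(array((s - 1) * w, c(dim(g$data), 3)), g$affine)
  jd <- jacobian_determinant(fs)
  core <- as.logical(get_core_mask(16))
  expect_lt(max(abs(jd$data[array(core, dim(g$data))] - s^3)), 1e-12)
  # brute-force 3x3 determinant oracle on a random smooth field
  f <- smooth_random_field(g, amp = 0.8, seed = 5)
  jd <- jacobian_determinant(f)
  J <- jacobian_matrix(f)$matrices
  idx <- sample(which(core), 50)
  for (i in idx) {
    m <- diag(3) + matrix(J[i, ], 3, 3)
    expect_equal(jd$data[i], det(m), tolerance = 1e-12)
  }
  # uniform affine displacement: det equals det of linear part everywhere
  A <- diag(c(0.02, -0.01, 0.015))
  fa <- as_field(array(t(A %*% t(w)), c(dim(g$data), 3)), g$affine)
  jda <- jacobian_determinant(fa)
  expect_lt(max(abs(jda$data[array(core, dim(g$data))] - det(diag(3) + A))),
            1e-12)
})
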