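# Spatio-temporal regularization of deformation trajectories.

mk_affine_linear_traj <- function(g, times) {
  # spatially affine, temporally linear: u(x, t) = (A + B t) x + c t
  w <- grid_world(g)
  A <- matrix(c(0.01, 0.02, 0, 0.005, -0.01, 0.01, 0, 0.01, 0.02), 3, 3)
  B <- matrix(c(0.01, 0, 0, 0, 0.015, 0, 0, 0, -0.01), 3, 3)
  fields <- lapply(times, function(t)
    as_field(array(t(A %*% t(w) + t * (B %*% t(w)) + c(1, 0, -0.5) * t),
                   c(dim(g$data), 3)), g$affine))
  new_trajectory(fields, times)
}

test_that("neighborhood-averaged Jacobians: affine exactness, impulse, radius 0", {
  g <- mk_grid(16, 2)
  times <- c(0, 0.5, 1, 2)
  traj <- mk_affine_linear_traj(g, times)
  jav <- jacobian_average(traj, radius = 1)
  raw <- jacobian_average(traj, radius = 0)
  core <- as.logical(get_core_mask(16))
  # averaging constant matrices changes nothing
  expect_lt(max(abs(jav[[2]]$matrices[core, ] - raw[[2]]$matrices[core, ])),
            1e-10)
  # radius 0 equals the raw jacobian
  expect_equal(raw[[1]]$matrices, jacobian_matrix(traj$fields[[1]])$matrices)
  # single-voxel impulse spreads at 1/27 of the raw derivative
  tz <- new_trajectory(lapply(times, function(t) zero_field(g)), times)
  tz$fields[[1]]$vectors[8, 8, 8, 1] <- 1
  ja <- jacobian_average(tz, 1)
  ra <- jacobian_average(tz, 0)
  i <- 8 + 16 * (7 + 16 * 7) + 1   # voxel (8,8,8), 1-based col-major
  expect_equal(ja[[1]]$matrices[i, 1], ra[[1]]$matrices[i, 1] / 27,
               tolerance = 1e-12)
})

test_that("temporal regression is exact on linear data", {
  g <- mk_grid(10, 2)
  times <- c(0, 0.5, 1, 2)
  a <- smooth_random_field(g, amp = 2, seed = 1)
  b <- smooth_random_field(g, amp = 0.7, seed = 2)
  traj <- new_trajectory(lapply(times, function(t)
    as_field(a$vectors + t * b$vectors, g$affine)), times)
  fit <- temporal_regression(traj)
  expect_lt(max(abs(fit$T0$vectors - a$vectors)), 1e-10)
  expect_lt(max(abs(fit$T1$vectors - b$vectors)), 1e-10)
  # constant trajectory: T0 = c, T1 = 0
  trc <- new_trajectory(lapply(times, function(t) a), times)
  fitc <- temporal_regression(trc)
  expect_lt(max(abs(fitc$T0$vectors - a$vectors)), 1e-12)
  expect_lt(max(abs(fitc$T1$vectors)), 1e-12)
  expect_error(new_trajectory(list(a, a), c(1, 1)), "increasing")
})

test_that("regularize passes affine/linear trajectories through exactly", {
  g <- mk_grid(16, 2)
  times <- c(0, 0.5, 1, 2)
  traj <- mk_affine_linear_traj(g, times)
  reg <- regularize(traj)
  err <- max(vapply(seq_along(times), function(j)
    max(abs(reg$fields[[j]]$vectors - traj$fields[[j]]$vectors)), 0))
  expect_lt(err / 2, 1e-3)     # within 1e-3 voxel
})

test_that("regularized outputs are exactly linear in time; 2 visits interpolate", {
  g <- mk_grid(10, 2)
  times <- c(0, 0.5, 1, 2)
  traj <- new_trajectory(lapply(seq_along(times), function(j)
    smooth_random_field(g, amp = 1.5, seed = j)), times)
  reg <- regularize(traj)
  # per voxel/component the 4 outputs lie exactly on a line in t
  resid <- 0
  for (j in seq_along(times)) {
    pred <- reg$T0$vectors + times[j] * reg$T1$vectors
    resid <- max(resid, max(abs(reg$fields[[j]]$vectors - pred)))
  }
  expect_lt(resid, 1e-8)
  # n = 2 regression passes through the (reconstructed) points
  tr2 <- new_trajectory(traj$fields[1:2], times[1:2])
  reg2 <- regularize(tr2)
  rec <- regularize(tr2, spatial = TRUE)  # same operator; check consistency
  for (j in 1:2)
    expect_lt(max(abs(reg2$fields[[j]]$vectors - rec$fields[[j]]$vectors)),
              1e-12)
})

test_that("voxel-wise mode is exactly idempotent; default mode at its fixed point", {
  g <- mk_grid(12, 2)
  times <- c(0, 0.5, 1, 2)
  traj <- new_trajectory(lapply(seq_along(times), function(j)
    smooth_random_field(g, amp = 2, seed = 10 + j)), times)
  r1 <- regularize(traj, spatial = FALSE)
  r2 <- regularize(r1, spatial = FALSE)
  err <- max(vapply(seq_along(times), function(j)
    max(abs(r2$fields[[j]]$vectors - r1$fields[[j]]$vectors)), 0))
  expect_lt(err, 1e-10)
  # the affine/linear class is a fixed point of the default operator
  ta <- mk_affine_linear_traj(mk_grid(16, 2), times)
  ra <- regularize(regularize(ta))
  err <- max(vapply(seq_along(times), function(j)
    max(abs(ra$fields[[j]]$vectors - ta$fields[[j]]$vectors)), 0))
  expect_lt(err / 2, 1e-3)
})

test_that("regularization suppresses independent per-visit noise and recovers slopes", {
  g <- mk_grid(16, 2)
  times <- c(0, 0.5, 1, 2)
  w <- grid_world(g)
  slope <- array(t(diag(c(0.03, 0.03, 0.03)) %*% t(w)), c(dim(g$data), 3))
  noisy <- lapply(seq_along(times), function(j) {
    nz <- smooth_random_field(g, amp = 0.2, fwhm_vox = 0.8, seed = 20 + j)
    as_field(slope * times[j] + nz$vectors, g$affine)
  })
  traj <- new_trajectory(noisy, times)
  reg <- regularize(traj)
  rms_in <- sqrt(mean(vapply(seq_along(times), function(j)
    mean((noisy[[j]]$vectors - slope * times[j])^2), 0)))
  rms_out <- sqrt(mean(vapply(seq_along(times), function(j)
    mean((reg$fields[[j]]$vectors - slope * times[j])^2), 0)))
  expect_lt(rms_out, rms_in)
  big <- abs(slope) > 0.3
  relerr <- median(abs(reg$T1$vectors[big] - slope[big]) / abs(slope[big]))
  expect_lt(relerr, 0.15)
})

test_that("noise variance after regularization respects the OLS leverage bound", {
  g <- mk_grid(8, 2)
  times <- c(0, 0.5, 1, 2)
  h <- 1 / 4 + (times - mean(times))^2 / sum((times - mean(times))^2)
  reps <- 100
  ratio <- matrix(NA_real_, reps, length(times))
  for (r in seq_len(reps)) {
    noisy <- lapply(seq_along(times), function(j) {
      set.seed(1000 * r + j)
      as_field(array(rnorm(prod(dim(g$data)) * 3, 0, 1),
                     c(dim(g$data), 3)), g$affine)
    })
    reg <- regularize(new_trajectory(noisy, times), spatial = FALSE)
    for (j in seq_along(times))
      ratio[r, j] <- var(as.numeric(reg$fields[[j]]$vectors))
  }
  # across 100 replicates the output variance per visit is close to h_jj
  for (j in seq_along(times))
    expect_lt(mean(ratio[, j]), h[j] * 1.1)
})
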