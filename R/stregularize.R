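#' Longitudinal deformation trajectory
#'
#' A trajectory stacks one displacement field per visit with the (strictly
#' increasing) visit times in years: the displacement of each template voxel
#' toward the anatomy of each visit, viewed as a function of time.
#'
#' @param fields list of `mdt_field` objects on a common grid, one per visit.
#' @param times numeric visit times in years, strictly increasing.
#' @return a `mdt_trajectory`.
#' @export
new_trajectory <- function(fields, times) {
  if (length(fields) != length(times) || length(fields) < 2)
    stop("a trajectory needs >= 2 fields with matching times")
  if (any(diff(times) <= 0)) stop("visit times must be strictly increasing")
  for (f in fields[-1]) if (!same_grid(fields[[1]], f))
    stop("trajectory fields must share a grid")
  structure(list(fields = fields, times = as.numeric(times),
                 T0 = NULL, T1 = NULL),
            class = "mdt_trajectory")
}

#' @exportS3Method print mdt_trajectory
print.mdt_trajectory <- function(x, ...) {
  cat(sprintf("<mdt_trajectory> %d visits at t = %s yr\n", length(x$fields),
              paste(signif(x$times, 3), collapse = ", ")))
  invisible(x)
}

#' Neighborhood-averaged Jacobian matrices of a trajectory
#'
#' For each visit, the finite-difference Jacobian of the displacement field
#' is averaged over the (2*radius+1)^3 neighborhood of every voxel
#' (truncated at the volume borders). `radius = 0` returns the raw Jacobians.
#'
#' @param traj a `mdt_trajectory`.
#' @param radius neighborhood radius in voxels (default 1, i.e. 3x3x3).
#' @return list of `mdt_jacobian`, one per visit.
#' @export
jacobian_average <- function(traj, radius = 1) {
  lapply(traj$fields, function(f) {
    J <- jacobian_matrix(f)
    if (radius > 0) {
      d <- J$dims
      for (c in seq_len(9))
        J$matrices[, c] <- cpp_boxmean(array(J$matrices[, c], d), d,
                                       as.integer(radius))
    }
    J
  })
}

#' Voxel-wise temporal regression of a trajectory
#'
#' Ordinary least squares of each displacement component against the actual
#' visit times, independently per voxel: returns the intercept field T0 (mm,
#' at t = 0) and slope field T1 (mm / year).
#'
#' @param traj a `mdt_trajectory`.
#' @return list with `T0` and `T1` (`mdt_field` objects; T1 holds mm/yr).
#' @export
temporal_regression <- function(traj) {
  tt <- traj$times
  if (anyDuplicated(tt)) stop("duplicate visit times")
  tm <- mean(tt)
  tc <- tt - tm
  sxx <- sum(tc^2)
  dims4 <- dim(traj$fields[[1]]$vectors)
  acc_mean <- array(0, dims4)
  acc_slope <- array(0, dims4)
  for (j in seq_along(tt)) {
    v <- traj$fields[[j]]$vectors
    acc_mean <- acc_mean + v
    acc_slope <- acc_slope + tc[j] * v
  }
  acc_mean <- acc_mean / length(tt)
  T1 <- acc_slope / sxx
  T0 <- acc_mean - tm * T1
  list(T0 = as_field(T0, traj$fields[[1]]$affine),
       T1 = as_field(T1, traj$fields[[1]]$affine))
}

#' Spatio-temporal regularization of a deformation trajectory
#'
#' The core longitudinal constraint: each visit's displacement field is first
#' reconstructed from its neighborhood through the first-order Taylor model
#' `mean over u in Omega_v of [T(u,t) + Jbar(u,t) (v - u)]` (with `Jbar` the
#' neighborhood-averaged Jacobian), which regularizes space while being exact
#' for spatially affine fields; the reconstructed displacements are then
#' regressed linearly against the visit times per voxel and component, and
#' the fitted values at the visit times replace the fields. With
#' `spatial = FALSE` the Taylor reconstruction is skipped and the operator
#' reduces to the pure voxel-wise temporal regression (which is exactly
#' idempotent for any input).
#'
#' @param traj a `mdt_trajectory`.
#' @param radius spatial neighborhood radius in voxels (default 1).
#' @param spatial apply the neighborhood Taylor reconstruction before the
#'   temporal regression (default TRUE).
#' @return a `mdt_trajectory` with regularized `fields` and populated
#'   `T0` / `T1`.
#' @export
regularize <- function(traj, radius = 1, spatial = TRUE) {
  stopifnot(inherits(traj, "mdt_trajectory"))
  work <- traj
  if (spatial && radius > 0) {
    jav <- jacobian_average(traj, radius)
    sp <- voxel_spacing(traj$fields[[1]])
    d <- dim(traj$fields[[1]]$vectors)[1:3]
    work$fields <- lapply(seq_along(traj$fields), function(j) {
      Tm <- matrix(traj$fields[[j]]$vectors, ncol = 3)
      R <- cpp_taylor_reconstruct(Tm, jav[[j]]$matrices, d,
                                  as.integer(radius), sp)
      as_field(array(R, dim(traj$fields[[j]]$vectors)),
               traj$fields[[j]]$affine)
    })
  }
  fit <- temporal_regression(work)
  out <- traj
  out$T0 <- fit$T0
  out$T1 <- fit$T1
  out$fields <- lapply(traj$times, function(t)
    as_field(fit$T0$vectors + t * fit$T1$vectors, fit$T0$affine))
  out
}
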