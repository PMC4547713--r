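#' Resample a volume through an affine transform or displacement field
#'
#' Pull-back resampling: for each voxel of the target grid with world
#' coordinate `w`, the source volume is sampled at `A %*% w` (affine) or
#' `w + u(w)` (displacement field). Values outside the source extent are 0,
#' matching skull-normalized images whose background is (near) zero.
#'
#' @param vol source `mdt_volume`.
#' @param xform a `mdt_affine`, a `mdt_field`, or `NULL` for identity.
#' @param grid target grid: a `mdt_volume` or `mdt_field` (its lattice and
#'   affine are used). Defaults to the grid of `xform` when it is a field,
#'   else the grid of `vol`.
#' @param order interpolation order: 1 (trilinear) or 4 (cubic 4-point
#'   convolution).
#' @return a `mdt_volume` on the target grid.
#' @export
resample <- function(vol, xform = NULL, grid = NULL, order = 1) {
  stopifnot(is_volume(vol))
  if (!order %in% c(1, 4)) stop("order must be 1 (trilinear) or 4 (cubic)")
  if (is.null(grid)) grid <- if (is_field(xform)) xform else vol
  gd <- if (is_volume(grid)) dim(grid$data) else dim(grid$vectors)[1:3]
  pts <- grid_world(grid)
  if (is.null(xform)) {
    # identity
  } else if (inherits(xform, "mdt_affine")) {
    pts <- cbind(pts, 1) %*% t(xform$matrix)
    pts <- pts[, 1:3, drop = FALSE]
  } else if (is_field(xform)) {
    if (!same_grid(xform, grid))
      stop("displacement field grid does not match the target grid")
    pts <- pts + matrix(xform$vectors, ncol = 3)
  } else stop("xform must be NULL, a mdt_affine or a mdt_field")
  vals <- cpp_sample_volume(vol$data, dim(vol$data), solve(vol$affine), pts,
                            as.integer(order))
  as_volume(array(vals, gd), grid$affine, vol$meta)
}

#' Sample a displacement field at arbitrary world points (trilinear)
#' @param field a `mdt_field`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of displacement vectors (mm); zero outside the grid.
#' @export
sample_field <- function(field, pts) {
  d <- dim(field$vectors)[1:3]
  ai <- solve(field$affine)
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3)
    out[, c] <- cpp_sample_volume(field$vectors[, , , c], d, ai, pts, 1L)
  out
}

#' Compose two displacement fields
#'
#' `compose(outer, inner)(x) = x + u_in(x) + u_out(x + u_in(x))`: the inner
#' displacement is applied first, then the outer field is sampled (trilinear)
#' at the displaced points. Both fields must live on the same grid.
#'
#' @param outer,inner `mdt_field` objects on a common grid.
#' @return the composed `mdt_field`.
#' @export
compose <- function(outer, inner) {
  stopifnot(is_field(outer), is_field(inner))
  if (!same_grid(outer, inner)) stop("fields must share a grid")
  pts <- grid_world(inner) + matrix(inner$vectors, ncol = 3)
  uo <- sample_field(outer, pts)
  as_field(array(matrix(inner$vectors, ncol = 3) + uo,
                 dim(inner$vectors)), inner$affine)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Iterates `u_inv <- -u(x + u_inv(x))` until the maximum update is below
#' `tol` (in voxels) or `max_iter` is reached. Non-convergence is flagged in
#' the attributes rather than raising an error.
#'
#' @param field a `mdt_field`.
#' @param tol convergence tolerance in voxel units (default 0.01).
#' @param max_iter maximum number of fixed-point iterations.
#' @return a `mdt_field` with attributes `converged` (logical) and `residual`
#'   (last maximum update, voxels).
#' @export
invert_field <- function(field, tol = 0.01, max_iter = 50) {
  vmin <- min(voxel_spacing(field))
  d <- dim(field$vectors)[1:3]
  r <- cpp_invert_field(field$vectors, d, solve(field$affine),
                        grid_world(field), tol * vmin, as.integer(max_iter))
  out <- as_field(array(r$vectors, dim(field$vectors)), field$affine)
  attr(out, "converged") <- r$residual / vmin < tol
  attr(out, "residual") <- r$residual / vmin
  out
}

#' Voxel-wise mean of displacement fields
#' @param fields non-empty list of `mdt_field` objects on a common grid.
#' @return the mean `mdt_field`.
#' @export
mean_field <- function(fields) {
  if (length(fields) < 1L) stop("mean_field needs at least one field")
  for (f in fields[-1]) if (!same_grid(fields[[1]], f))
    stop("fields must share a grid")
  acc <- fields[[1]]$vectors
  for (f in fields[-1]) acc <- acc + f$vectors
  as_field(acc / length(fields), fields[[1]]$affine)
}

#' Jacobian matrix field of a displacement field
#'
#' Spatial derivatives of the displacement (dimensionless), by central finite
#' differences in the interior and one-sided differences at the boundary,
#' with respect to world mm along each grid axis.
#'
#' @param field a `mdt_field` with at least 3 voxels per axis.
#' @return a `mdt_jacobian`: list with `matrices` (nvox x 9 matrix, entry
#'   (r, c) of the 3x3 stored at column r + 3(c-1)), `dims` and `affine`.
#' @export
jacobian_matrix <- function(field) {
  stopifnot(is_field(field))
  d <- dim(field$vectors)[1:3]
  if (any(d < 3L)) stop("jacobian needs >= 3 voxels per axis")
  J <- cpp_jacobian(field$vectors, d, voxel_spacing(field))
  structure(list(matrices = J, dims = d, affine = field$affine),
            class = "mdt_jacobian")
}

#' Jacobian determinant map of a deformation
#'
#' Local volume-change factor `det(I + grad u)` of the transform
#' `x -> x + u(x)`. Values below zero indicate folding and are counted in the
#' `n_negative` attribute.
#'
#' @param field a `mdt_field` (or a precomputed `mdt_jacobian`).
#' @return a `mdt_volume` of determinants with attribute `n_negative`.
#' @export
jacobian_determinant <- function(field) {
  J <- if (inherits(field, "mdt_jacobian")) field else jacobian_matrix(field)
  m <- J$matrices
  a11 <- 1 + m[, 1]; a21 <- m[, 2]; a31 <- m[, 3]
  a12 <- m[, 4]; a22 <- 1 + m[, 5]; a32 <- m[, 6]
  a13 <- m[, 7]; a23 <- m[, 8]; a33 <- 1 + m[, 9]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  out <- as_volume(array(det, J$dims), J$affine)
  attr(out, "n_negative") <- sum(det <= 0)
  out
}

#' Gaussian smoothing of a volume or of a field's components
#'
#' @param x a `mdt_volume` or `mdt_field`.
#' @param fwhm full-width-half-maximum of the kernel in mm (scalar or per
#'   axis).
#' @param zeropad treat values outside the lattice as zero (default reflects
#'   at the boundary).
#' @return object of the same class, smoothed.
#' @export
smooth_gaussian <- function(x, fwhm, zeropad = FALSE) {
  sig <- (rep(fwhm, length.out = 3) / 2.354820045) / voxel_spacing(x)
  if (is_volume(x)) {
    x$data <- array(cpp_gaussian_blur(x$data, dim(x$data), sig, zeropad),
                    dim(x$data))
    x
  } else {
    d <- dim(x$vectors)[1:3]
    for (c in 1:3)
      x$vectors[, , , c] <- array(
        cpp_gaussian_blur(x$vectors[, , , c], d, sig, zeropad), d)
    x
  }
}
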