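#' Image volume, affine transform and displacement field containers
#'
#' A `mdt_volume` is a 3D scalar lattice together with a 4x4 voxel-to-world
#' affine (0-based voxel indices, world coordinates in mm) and free-form
#' metadata. A `mdt_affine` is a 4x4 homogeneous world-to-world matrix used as
#' a pull-back map: resampling a source image onto a grid samples the source
#' at `A %*% w` for each grid world coordinate `w`. A `mdt_field` stores a
#' dense displacement field on a reference grid, with vectors in world mm and
#' the same pull-back convention (sample the source at `w + u(w)`).
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param meta optional list of metadata.
#' @return `as_volume` returns a `mdt_volume` object.
#' @export
as_volume <- function(data, affine = diag(4), meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 2L)) stop("volume must have >= 2 voxels per axis")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  if (!all(is.finite(data))) stop("volume values must be finite")
  structure(list(data = data, affine = affine, meta = meta),
            class = "mdt_volume")
}

#' @rdname as_volume
#' @param x object to test or print.
#' @export
is_volume <- function(x) inherits(x, "mdt_volume")

#' @exportS3Method print mdt_volume
print.mdt_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- voxel_spacing(x)
  cat(sprintf("<mdt_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @exportS3Method dim mdt_volume
dim.mdt_volume <- function(x) dim(x$data)

#' Voxel spacing of a volume or field grid (mm per axis)
#' @param x a `mdt_volume` or `mdt_field`.
#' @return numeric length-3 vector of mm step sizes.
#' @export
voxel_spacing <- function(x) {
  a <- x$affine[1:3, 1:3]
  sqrt(colSums(a^2))
}

#' World coordinates of every voxel of a grid
#'
#' Returns an n-voxel x 3 matrix of world (mm) coordinates in column-major
#' voxel order.
#' @param x a `mdt_volume` or `mdt_field`.
#' @return numeric matrix (nvox x 3).
#' @export
grid_world <- local({
  cache <- new.env(parent = emptyenv())
  function(x) {
    d <- if (is_volume(x)) dim(x$data) else dim(x$vectors)[1:3]
    key <- paste(c(d, signif(x$affine, 12)), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ijk <- cbind(
      rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
      rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
      rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
      1
    )
    w <- (ijk %*% t(x$affine))[, 1:3, drop = FALSE]
    if (length(ls(cache)) > 16) rm(list = ls(cache), envir = cache)
    cache[[key]] <- w
    w
  }
})

#' Construct an affine world-to-world transform
#'
#' @param matrix 4x4 homogeneous matrix; last row must be (0,0,0,1).
#' @param dof one of `"rigid6"`, `"similarity9"`, `"affine12"`.
#' @return a `mdt_affine` object.
#' @export
as_affine <- function(matrix, dof = "affine12") {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4L, 4L))) stop("affine must be 4x4")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last row of an affine transform must be (0,0,0,1)")
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("affine is singular")
  dof <- match.arg(dof, c("rigid6", "similarity9", "affine12"))
  structure(list(matrix = matrix, dof = dof), class = "mdt_affine")
}

#' @exportS3Method print mdt_affine
print.mdt_affine <- function(x, ...) {
  cat(sprintf("<mdt_affine> %s\n", x$dof))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Construct a displacement field
#'
#' @param vectors 4D array (nx, ny, nz, 3) of world-mm displacements under the
#'   pull-back convention.
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @return a `mdt_field` object.
#' @export
as_field <- function(vectors, affine = diag(4)) {
  vectors <- as.array(vectors)
  dv <- dim(vectors)
  if (length(dv) != 4L || dv[4] != 3L)
    stop("field vectors must be an (nx, ny, nz, 3) array")
  if (!all(is.finite(vectors))) stop("field vectors must be finite")
  structure(list(vectors = vectors, affine = as.matrix(affine)),
            class = "mdt_field")
}

#' @rdname as_field
#' @param x object to test.
#' @export
is_field <- function(x) inherits(x, "mdt_field")

#' @exportS3Method print mdt_field
print.mdt_field <- function(x, ...) {
  d <- dim(x$vectors)
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat(sprintf("<mdt_field> %d x %d x %d grid, |u| max %.3g mm, mean %.3g mm\n",
              d[1], d[2], d[3], max(mag), mean(mag)))
  invisible(x)
}

#' Zero displacement field on the grid of a volume
#' @param grid a `mdt_volume` (or `mdt_field`) defining the lattice.
#' @return a `mdt_field` of zeros.
#' @export
zero_field <- function(grid) {
  d <- if (is_volume(grid)) dim(grid$data) else dim(grid$vectors)[1:3]
  as_field(array(0, c(d, 3L)), grid$affine)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (is_volume(a)) dim(a$data) else dim(a$vectors)[1:3]
  db <- if (is_volume(b)) dim(b$data) else dim(b$vectors)[1:3]
  all(da == db) && max(abs(a$affine - b$affine)) < tol
}

#' Read and write volumes, masks and displacement fields as NIfTI-1
#'
#' Volumes are stored as 3D NIfTI with the affine in the sform; displacement
#' fields as 4D NIfTI whose 4th dimension holds the 3 vector components
#' (x, y, z order, mm units); masks as uint8. Both plain `.nii` and gzipped
#' `.nii.gz` files are accepted.
#'
#' @param path file path.
#' @param vol,field,mask objects to write.
#' @return readers return the corresponding object; writers return the path
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  as_volume(a, structure(RNifti::xform(img), imagedim = NULL, code = NULL)[1:4, 1:4])
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("displacement field NIfTI must be 4D with 3 vector components: ",
         path, " has dims ", paste(dim(a), collapse = "x"))
  as_field(a, structure(RNifti::xform(img), imagedim = NULL, code = NULL)[1:4, 1:4])
}

#' @rdname read_volume
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$vectors)
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  v$data <- (v$data > 0.5) * 1
  v
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data > 0.5), dim(mask$data)),
                         datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
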