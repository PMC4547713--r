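# Shared fixtures: tiny analytic grids and seeded smooth random fields.

mk_grid <- function(n = 16, vox = 2, offset = -vox * (n - 1) / 2) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- offset
  as_volume(array(0, rep(n, 3)), aff)
}

# smooth zero-mean random field with approximate amplitude `amp` (mm)
smooth_random_field <- function(grid, amp = 1, fwhm_vox = 1.5, seed = 1) {
  set.seed(seed)
  d <- dim(grid$data)
  u <- array(rnorm(prod(d) * 3), c(d, 3))
  f <- as_field(u, grid$affine)
  f <- smooth_gaussian(f, fwhm_vox * voxel_spacing(grid)[1])
  f$vectors <- f$vectors / max(sd(f$vectors), 1e-12) * amp
  f
}

# ramp volume increasing along x (values = voxel index)
ramp_volume <- function(n = 16, vox = 2) {
  g <- mk_grid(n, vox)
  g$data <- array(rep(seq_len(n), n * n), rep(n, 3))
  g
}

# isotropic Gaussian blob, analytic
blob_volume <- function(n = 16, vox = 2, sigma_mm = 8, amp = 100) {
  g <- mk_grid(n, vox)
  w <- grid_world(g)
  g$data <- array(amp * exp(-rowSums(w^2) / (2 * sigma_mm^2)), rep(n, 3))
  g
}

# column-major logical vector marking voxels at least `margin` from borders
get_core_mask <- function(n, margin = 3) {
  idx <- seq_len(n)
  inside <- idx > margin & idx <= n - margin
  as.vector(outer(outer(inside, inside, `&`), inside, `&`))
}

test_spec <- function(seed = 42, ...) phantom_spec(seed = seed, ...)

# single shared phantom for moderately expensive checks
.fixture_env <- new.env()
get_phantom <- function(texture = FALSE) {
  key <- paste0("ph_", texture)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_phantom(test_spec(), texture = texture)
  .fixture_env[[key]]
}
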