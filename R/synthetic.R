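#' Specification of a 4D ground-truth brain phantom
#'
#' Defines the geometry, intensities, per-structure atrophy rates and
#' acquisition artifacts (Rician noise, multiplicative bias field, rigid
#' positioning jitter) of a piecewise-smooth digital phantom with a brain
#' ellipsoid, two lateral-ventricle lobes and two hippocampal blobs. The
#' defaults emulate a 1.5T T1w protocol at desk scale: a 48^3 lattice of
#' 2.5 mm voxels, intensities on the 0-100 scale and annual volume-change
#' rates close to published ADNI-1 estimates (brain and hippocampal atrophy,
#' ventricular growth).
#'
#' @param grid_size voxels per axis (cubic lattice).
#' @param voxel_size voxel edge in mm.
#' @param noise_sigma Rician noise sigma on the 0-100 intensity scale.
#' @param bias_amp log-amplitude (sd) of the multiplicative bias field.
#' @param bias_fwhm spatial scale of the bias field in mm.
#' @param jitter_mm,jitter_deg half-ranges of the per-scan rigid jitter.
#' @param subject_sd sd of the per-subject log radii perturbation.
#' @param texture_amp amplitude of the smooth intra-brain intensity texture.
#' @param edge_mm width of the anti-aliased structure boundaries in mm.
#' @param seed mandatory master seed; all randomness derives from it.
#' @return a `phantom_spec` list, including the `structures` geometry table.
#' @export
phantom_spec <- function(grid_size = 48, voxel_size = 2.5, noise_sigma = 3,
                         bias_amp = 0.05, bias_fwhm = 60, jitter_mm = 2,
                         jitter_deg = 2, subject_sd = 0.02, texture_amp = 8,
                         edge_mm = 3, seed) {
  if (missing(seed)) stop("phantom_spec: a seed is mandatory")
  structures <- list(
    brain = list(
      centers = rbind(c(0.4, -0.3, 0.2)), radii = rbind(c(44, 52, 42)),
      intensity = 70, mode = "shell", band = c(0.88, 0.94, 1.06, 1.20)),
    ventricles = list(
      centers = rbind(c(-11.3, 9.6, 4.2), c(10.8, 10.4, 3.7)),
      radii = rbind(c(8, 12, 8), c(8, 12, 8)),
      intensity = 12, mode = "solid", band = c(1.18, 1.38)),
    hippocampus_l = list(
      centers = rbind(c(-17.1, -13.9, -6.6)), radii = rbind(c(7.5, 10.5, 7.5)),
      intensity = 50, mode = "solid", band = c(1.10, 1.27)),
    hippocampus_r = list(
      centers = rbind(c(16.8, -14.2, -7.1)), radii = rbind(c(7.5, 10.5, 7.5)),
      intensity = 50, mode = "solid", band = c(1.10, 1.27))
  )
  structure(list(grid_size = grid_size, voxel_size = voxel_size,
                 structures = structures, noise_sigma = noise_sigma,
                 bias_amp = bias_amp, bias_fwhm = bias_fwhm,
                 jitter_mm = jitter_mm, jitter_deg = jitter_deg,
                 subject_sd = subject_sd, texture_amp = texture_amp,
                 edge_mm = edge_mm, seed = seed),
            class = "phantom_spec")
}

# evaluate expr under a temporary seed, restoring the global RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed %% 2147483647)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

phantom_affine <- function(spec) {
  n <- spec$grid_size
  a <- diag(c(rep(spec$voxel_size, 3), 1))
  a[1:3, 4] <- -spec$voxel_size * (n - 1) / 2
  a
}

# Ellipsoid "distance" of world points to one lobe: 1 on the surface.
lobe_d <- function(pts, center, radii) {
  sqrt(((pts[, 1] - center[1]) / radii[1])^2 +
       ((pts[, 2] - center[2]) / radii[2])^2 +
       ((pts[, 3] - center[3]) / radii[3])^2)
}

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Atrophy support weight as a function of ellipsoid distance d.
# solid: 1 inside the structure and its rim (d <= band[1]), smooth falloff to
# zero at band[2]; shell: nonzero only near the boundary (ramp up over
# band[1:2], plateau, down over band[3:4]) so nested structures are
# untouched. The plateau must cover the scaled surface position.
atrophy_weight <- function(d, mode, band) {
  if (mode == "solid") {
    1 - smoothstep((d - band[1]) / (band[2] - band[1]))
  } else {
    smoothstep((d - band[1]) / (band[2] - band[1])) *
      (1 - smoothstep((d - band[3]) / (band[4] - band[3])))
  }
}

# Displacement (n x 3, mm) of the radial scaling of one structure at world
# points; scale = target linear scale factor s; inverse=TRUE gives the
# pull-back used for image synthesis (scale 1/s evaluated in warped space).
structure_scaling <- function(pts, st, scale) {
  out <- matrix(0, nrow(pts), 3)
  for (l in seq_len(nrow(st$centers))) {
    d <- lobe_d(pts, st$centers[l, ], st$radii[l, ])
    w <- atrophy_weight(d, st$mode, st$band)
    nz <- w > 0
    if (any(nz)) {
      f <- (scale - 1) * w[nz]
      out[nz, 1] <- out[nz, 1] + f * (pts[nz, 1] - st$centers[l, 1])
      out[nz, 2] <- out[nz, 2] + f * (pts[nz, 2] - st$centers[l, 2])
      out[nz, 3] <- out[nz, 3] + f * (pts[nz, 3] - st$centers[l, 3])
    }
  }
  out
}

# per-structure linear scale factor from a volume-change rate (% / yr)
rate_to_scale <- function(rate, t) {
  ratio <- 1 - rate * t / 100
  if (ratio <= 0.7 || ratio >= 1.43)
    stop("atrophy rate x time outside the valid (invertible) range")
  ratio^(1 / 3)
}

subject_geometry <- function(spec, max_tries = 20) {
  # per-subject perturbation of the base geometry (draws from the current
  # RNG stream); redraws in the rare case the structure supports collide
  for (try in seq_len(max_tries)) {
    st <- spec$structures
    for (nm in names(st)) {
      sc <- exp(rnorm(1, 0, spec$subject_sd))
      st[[nm]]$radii <- st[[nm]]$radii * sc
      st[[nm]]$centers <- st[[nm]]$centers +
        matrix(runif(length(st[[nm]]$centers), -1, 1), nrow(st[[nm]]$centers), 3)
    }
    if (geometry_ok(spec, st)) return(st)
  }
  stop("could not draw a non-overlapping subject geometry")
}

geometry_ok <- function(spec, st) {
  aff <- phantom_affine(spec)
  n <- spec$grid_size
  pts <- grid_world(as_volume(array(0, rep(n, 3)), aff))
  supp <- lapply(st, function(s) {
    w <- rep(0, nrow(pts))
    for (l in seq_len(nrow(s$centers)))
      w <- pmax(w, atrophy_weight(lobe_d(pts, s$centers[l, ], s$radii[l, ]),
                                  s$mode, s$band))
    w > 1e-6
  })
  inner <- names(st)[-1]
  # nested structures must avoid the brain shell and each other
  for (i in seq_along(inner)) {
    if (any(supp[[inner[i]]] & supp[["brain"]])) return(FALSE)
    if (i < length(inner))
      for (j in seq((i + 1), length(inner)))
        if (any(supp[[inner[i]]] & supp[[inner[j]]])) return(FALSE)
  }
  TRUE
}

#' Build a static phantom volume and its structure masks
#'
#' Evaluates the piecewise-smooth intensity model (anti-aliased ellipsoid
#' boundaries, optional smooth intra-brain texture) on the lattice and
#' returns binary masks for every structure. Deterministic given the seed.
#'
#' @param spec a [phantom_spec()].
#' @param geometry optional per-subject geometry (defaults to the base
#'   geometry of `spec`).
#' @param texture include the seeded smooth texture (default TRUE).
#' @param texture_seed seed of the texture draw (default `spec$seed`); the
#'   global RNG stream is left untouched.
#' @return list with `volume` (`mdt_volume`), `masks` (named list of binary
#'   `mdt_volume`), `geometry`.
#' @export
make_phantom <- function(spec, geometry = NULL, texture = TRUE,
                         texture_seed = spec$seed) {
  st <- if (is.null(geometry)) spec$structures else geometry
  if (!geometry_ok(spec, st))
    stop("make_phantom: structure supports overlap")
  aff <- phantom_affine(spec)
  n <- spec$grid_size
  dims <- rep(n, 3)
  vol0 <- as_volume(array(0, dims), aff)
  pts <- grid_world(vol0)
  img <- phantom_intensity(spec, st, pts)
  masks <- list()
  for (nm in names(st)) {
    s <- st[[nm]]
    dmin <- rep(Inf, nrow(pts))
    for (l in seq_len(nrow(s$centers)))
      dmin <- pmin(dmin, lobe_d(pts, s$centers[l, ], s$radii[l, ]))
    # the brain mask is the whole enclosed region (inner structures are
    # nested inside it): its volume is governed by the outer surface alone,
    # which keeps Jacobian integration well-posed; the inner structures are
    # pairwise disjoint
    masks[[nm]] <- as_volume(array(as.numeric(dmin <= 1), dims), aff)
  }
  if (texture && spec$texture_amp > 0) {
    tex <- with_local_seed(texture_seed, array(rnorm(prod(dims)), dims))
    sig <- rep(12 / 2.3548 / spec$voxel_size, 3)
    tex <- array(cpp_gaussian_blur(tex, dims, sig, FALSE), dims)
    tex <- tex / max(sd(tex), 1e-12) * spec$texture_amp
    db <- lobe_d(pts, st$brain$centers[1, ], st$brain$radii[1, ])
    inside <- 1 - smoothstep((db - 0.7) / 0.15)
    img <- img + as.numeric(tex) * inside
  }
  list(volume = as_volume(array(pmax(img, 0), dims), aff),
       masks = masks, geometry = st)
}

phantom_intensity <- function(spec, st, pts) {
  ew <- function(s) spec$edge_mm / exp(mean(log(s$radii[1, ])))
  img <- rep(0, nrow(pts))
  b <- st$brain
  db <- lobe_d(pts, b$centers[1, ], b$radii[1, ])
  img <- img + b$intensity * (1 - smoothstep((db - 1) / ew(b) + 0.5))
  for (nm in setdiff(names(st), "brain")) {
    s <- st[[nm]]
    chi <- rep(0, nrow(pts))
    for (l in seq_len(nrow(s$centers))) {
      d <- lobe_d(pts, s$centers[l, ], s$radii[l, ])
      chi <- pmax(chi, 1 - smoothstep((d - 1) / ew(s) + 0.5))
    }
    img <- img + (s$intensity - b$intensity) * chi
  }
  img
}

#' Analytic ground-truth atrophy field of one structure
#'
#' Pull-back displacement field (template -> visit) of the compactly
#' supported radial scaling that changes the structure volume by exactly
#' `1 - rate * t / 100`: the scaling is exact in a band covering the
#' structure boundary, so the enclosed (mask) volume scales by `s^3` with
#' `s = (1 - rate * t / 100)^(1/3)`. Ventricular growth uses a negative
#' rate. The field is smooth and invertible for `|rate * t| < 30`.
#'
#' @param spec a [phantom_spec()].
#' @param structure structure name in `spec$structures`.
#' @param t time in years.
#' @param rate volume-change rate in percent per year (positive = loss).
#' @param geometry optional subject geometry.
#' @return a `mdt_field` on the phantom grid.
#' @export
atrophy_field <- function(spec, structure, t, rate, geometry = NULL) {
  st <- if (is.null(geometry)) spec$structures else geometry
  if (!structure %in% names(st)) stop("unknown structure: ", structure)
  s <- rate_to_scale(rate, t)
  aff <- phantom_affine(spec)
  dims <- rep(spec$grid_size, 3)
  pts <- grid_world(as_volume(array(0, dims), aff))
  u <- structure_scaling(pts, st[[structure]], s)
  as_field(array(u, c(dims, 3)), aff)
}

# total ground-truth generator displacement (pull-back used for synthesis):
# inverse scaling 1/s evaluated at visit-space points
generator_field_at <- function(pts, st, scales) {
  u <- matrix(0, nrow(pts), 3)
  for (nm in names(scales)) {
    s <- scales[[nm]]
    if (abs(s - 1) < 1e-12) next
    u <- u + structure_scaling(pts, st[[nm]], 1 / s)
  }
  u
}

rigid_jitter <- function(spec) {
  p <- c(runif(3, -spec$jitter_mm, spec$jitter_mm),
         runif(3, -spec$jitter_deg, spec$jitter_deg))
  params_to_matrix(p, c(0, 0, 0))
}

bias_field_draw <- function(spec, dims) {
  z <- array(rnorm(prod(dims)), dims)
  sig <- rep(spec$bias_fwhm / 2.3548 / spec$voxel_size, 3)
  z <- array(cpp_gaussian_blur(z, dims, sig, FALSE), dims)
  z <- z / max(sd(z), 1e-12)
  exp(spec$bias_amp * z)
}

# Synthesize one scan: anatomy warped by the structure scalings, rigid
# jitter, multiplicative bias and Rician noise.
synthesize_visit <- function(spec, clean, geometry, scales, jitter = TRUE,
                             noise = TRUE, bias = TRUE) {
  dims <- dim(clean$data)
  pts <- grid_world(clean)
  R <- if (jitter) rigid_jitter(spec) else diag(4)
  p1 <- cbind(pts, 1) %*% t(R)
  p1 <- p1[, 1:3, drop = FALSE]
  p2 <- p1 + generator_field_at(p1, geometry, scales)
  vals <- cpp_sample_volume(clean$data, dims, solve(clean$affine), p2, 4L)
  if (bias && spec$bias_amp > 0) vals <- vals * as.numeric(bias_field_draw(spec, dims))
  if (noise && spec$noise_sigma > 0) {
    n1 <- rnorm(length(vals), 0, spec$noise_sigma)
    n2 <- rnorm(length(vals), 0, spec$noise_sigma)
    vals <- sqrt((vals + n1)^2 + n2^2)
  }
  as_volume(array(pmax(vals, 0), dims), clean$affine,
            meta = list(jitter = R))
}

#' Simulate a scan-rescan dataset (no true anatomical change)
#'
#' Each subject is a phantom with slight individual geometry, scanned
#' `n_scans` times within one week: independent Rician noise, bias fields and
#' small rigid repositioning per scan, zero true volume change.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects,n_scans design size (defaults 20 x 4).
#' @param times scan times in years (same-week spacing by default).
#' @return a `mdt_dataset` list with `reference` (clean population phantom +
#'   masks), `subjects` (scans, stereotaxic-space masks, ground truth).
#' @export
simulate_scan_rescan <- function(spec, n_subjects = 20, n_scans = 4,
                                 times = c(0, 2, 5, 7) / 365.25) {
  times <- times[seq_len(n_scans)]
  set.seed(spec$seed %% 2147483647)
  ref <- make_phantom(spec, texture = FALSE)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    geom <- subject_geometry(spec)
    ph <- make_phantom(spec, geometry = geom, texture = TRUE,
                       texture_seed = (spec$seed + 7919L * i) %% 2147483647)
    scans <- lapply(seq_len(n_scans), function(j)
      synthesize_visit(spec, ph$volume, geom,
                       scales = list(), jitter = TRUE))
    subjects[[i]] <- list(id = sprintf("S%02d", i), group = "NC",
                          times = times, scans = scans, masks = ph$masks,
                          geometry = geom,
                          truth = list(rates = setNames(
                            rep(0, length(spec$structures)),
                            names(spec$structures))))
  }
  structure(list(kind = "scan_rescan", spec = spec, reference = ref,
                 subjects = subjects),
            class = "mdt_dataset")
}

#' Simulate an ADNI-like two-group longitudinal cohort
#'
#' Visits at 0/6/12/24 months by default; each subject receives individual
#' annual volume-change rates (group mean + between-subject sd) per
#' structure, realized as calibrated radial scaling fields plus noise, bias
#' and jitter. The returned truth table holds the noise-free longitudinal
#' percent volume change (`longVC = rate * t`).
#'
#' @param spec a [phantom_spec()].
#' @param n_nc,n_ad subjects per group.
#' @param rates_nc,rates_ad named per-structure mean rates (percent/yr,
#'   positive = volume loss; ventricles negative = growth).
#' @param rate_sd named between-subject sd of the rates.
#' @param times visit times in years.
#' @param noise,bias,jitter toggles for the acquisition artifacts.
#' @return a `mdt_dataset` with an added `truth_table` data frame.
#' @export
simulate_cohort <- function(spec, n_nc = 25, n_ad = 25,
                            rates_nc = c(brain = 0.66, ventricles = -3.86,
                                         hippocampus_l = 0.93,
                                         hippocampus_r = 0.82),
                            rates_ad = c(brain = 1.84, ventricles = -9.04,
                                         hippocampus_l = 3.38,
                                         hippocampus_r = 3.43),
                            rate_sd = c(brain = 0.35, ventricles = 1.8,
                                        hippocampus_l = 0.9,
                                        hippocampus_r = 0.9),
                            times = c(0, 0.5, 1, 2), noise = TRUE,
                            bias = TRUE, jitter = TRUE) {
  set.seed(spec$seed %% 2147483647)
  ref <- make_phantom(spec, texture = FALSE)
  n_tot <- n_nc + n_ad
  subjects <- vector("list", n_tot)
  rows <- list()
  for (i in seq_len(n_tot)) {
    grp <- if (i <= n_nc) "NC" else "AD"
    mu <- if (grp == "NC") rates_nc else rates_ad
    geom <- subject_geometry(spec)
    ph <- make_phantom(spec, geometry = geom, texture = TRUE,
                       texture_seed = (spec$seed + 7919L * i) %% 2147483647)
    rates <- setNames(mu[names(spec$structures)] +
                        rnorm(length(mu), 0, rate_sd[names(spec$structures)]),
                      names(spec$structures))
    scans <- vector("list", length(times))
    for (j in seq_along(times)) {
      scales <- lapply(rates, rate_to_scale, t = times[j])
      scans[[j]] <- synthesize_visit(spec, ph$volume, geom, scales,
                                     jitter = jitter, noise = noise,
                                     bias = bias)
    }
    subjects[[i]] <- list(id = sprintf("S%02d", i), group = grp,
                          times = times, scans = scans, masks = ph$masks,
                          geometry = geom, truth = list(rates = rates))
    for (nm in names(rates))
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("S%02d", i), group = grp, time = times,
        structure = nm, true_longvc = rates[[nm]] * times)
  }
  structure(list(kind = "cohort", spec = spec, reference = ref,
                 subjects = subjects,
                 truth_table = do.call(rbind, rows)),
            class = "mdt_dataset")
}

#' @exportS3Method print mdt_dataset
print.mdt_dataset <- function(x, ...) {
  cat(sprintf("<mdt_dataset> %s: %d subjects x %d visits, %d^3 voxels\n",
              x$kind, length(x$subjects), length(x$subjects[[1]]$times),
              x$spec$grid_size))
  invisible(x)
}
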