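#' Hierarchical non-linear registration schedule
#'
#' Per-level parameters of the node-based registration: node step size,
#' image blurring FWHM, local-correlation neighborhood diameter (all mm) and
#' the number of update iterations at the level. The default follows the
#' classic coarse-to-fine ladder 16/8/4/2/1 mm; desk-scale phantom work
#' typically truncates at 4 or 2 mm (`max_level_mm`).
#'
#' @param max_level_mm drop levels with a step size below this value.
#' @return data frame with columns `step`, `blur`, `neighborhood`,
#'   `iterations`.
#' @export
default_schedule <- function(max_level_mm = 1) {
  s <- data.frame(step = c(16, 8, 4, 2, 1),
                  blur = c(8, 4, 2, 1, 1),
                  neighborhood = c(48, 24, 12, 6, 6),
                  iterations = c(1, 2, 2, 2, 2))
  s[s$step >= max_level_mm, , drop = FALSE]
}

#' Compact schedule for desk-scale phantoms
#'
#' Two levels (8 and 4 mm) with two iterations each: at 48^3 / 2.5 mm the
#' linear stages already align the series to within a voxel or two, so the
#' 16 mm level adds cost without information.
#' @return schedule data frame as in [default_schedule()].
#' @export
phantom_schedule <- function() {
  data.frame(step = c(8, 4), blur = c(4, 2), neighborhood = c(24, 12),
             iterations = c(2, 2))
}

check_schedule <- function(schedule) {
  stopifnot(all(c("step", "blur", "neighborhood", "iterations") %in%
                  names(schedule)))
  if (any(diff(schedule$step) >= 0))
    stop("schedule step sizes must be strictly decreasing")
  if (any(schedule$neighborhood < schedule$step))
    stop("schedule neighborhood must be >= step size")
  schedule
}

#' Non-linear registration at one schedule level
#'
#' Demons-flavoured surrogate of grid-node matching: both images are blurred
#' at the level's FWHM; on a node lattice spaced at the step size, each
#' node's displacement update is found by discrete local search (+/- one
#' voxel per axis per iteration, with per-axis quadratic refinement)
#' maximizing the local cross-correlation over the neighborhood cube. Node updates are
#' interpolated to a dense field, smoothed with a Gaussian of FWHM equal to
#' the step size (the elastic surrogate), and composed with the current
#' field. Constant (degenerate) neighborhoods contribute no update.
#'
#' @param src,tgt intensity-normalized `mdt_volume` objects on one grid.
#' @param level one row of a [default_schedule()] (list or data frame row).
#' @param init optional initial `mdt_field` (warm start).
#' @param min_sd intensity sd below which a neighborhood counts as constant.
#' @param min_gain minimum local cross-correlation improvement required to
#'   accept a node shift (guards against the aperture problem along
#'   homogeneous boundaries).
#' @param gain_soft optional soft-confidence scale (0 disables): node
#'   offsets are weighted by gain / (gain + gain_soft).
#' @param relax optional under-relaxation factor for the dense update.
#' @param smooth_factor multiple of the step size used as the update
#'   smoothing FWHM.
#' @return a `mdt_field` mapping the target grid into the source (pull-back).
#' @export
register_nonlinear <- function(src, tgt, level, init = NULL, min_sd = 2,
                               min_gain = 1e-4, gain_soft = 0,
                               relax = 0.6, smooth_factor = 1) {
  stopifnot(is_volume(src), is_volume(tgt))
  if (!same_grid(src, tgt)) stop("src and tgt must share a grid")
  level <- as.list(level)
  sp <- voxel_spacing(tgt)
  dims <- dim(tgt$data)
  # resolution floors: below ~1 voxel the blur and update smoothing no
  # longer regularize and voxel-level aliasing drives spurious updates
  blur_eff <- max(level$blur, 1.2 * min(sp))
  smooth_eff <- max(smooth_factor * level$step, 2 * min(sp))
  srcb <- if (is.null(attr(src, "preblurred"))) smooth_gaussian(src, blur_eff)
          else src
  tgtb <- if (is.null(attr(tgt, "preblurred"))) smooth_gaussian(tgt, blur_eff)
          else tgt
  u <- if (is.null(init)) zero_field(tgt) else init
  stepvox <- pmax(1L, as.integer(round(level$step / sp)))
  shiftvox <- rep(max(0.25, min(1, level$step / 2 / min(sp))), 3)
  # search is at most one voxel per iteration, refined subvoxel; fine levels
  # use fractional steps matched to step/2
  radvox <- pmax(1L, as.integer(round(level$neighborhood / 2 / sp)))
  stridevox <- pmax(1L, as.integer(round(level$step / 2 / sp)))
  node_aff <- tgt$affine %*% diag(c(stepvox, 1))
  pts <- grid_world(tgt)
  ndims <- as.integer((dims + stepvox - 1) %/% stepvox)
  for (it in seq_len(level$iterations)) {
    srcw <- resample(srcb, u, u, order = 1)
    nodes <- cpp_node_search(srcw$data, tgtb$data, dims, stepvox, shiftvox,
                             radvox, stridevox, min_sd, min_gain, gain_soft)
    nodes <- array(nodes, c(ndims, 3L))
    du <- matrix(0, nrow(pts), 3)
    nai <- solve(node_aff)
    for (c in 1:3)
      du[, c] <- cpp_sample_volume(nodes[, , , c] * sp[c], ndims, nai, pts, 1L)
    duf <- smooth_gaussian(as_field(array(relax * du, c(dims, 3L)),
                                    tgt$affine), smooth_eff)
    # trust region: one smoothed update may not exceed half a voxel per
    # component, keeping the fixed-point iteration contractive
    cap <- 0.5 * sp
    for (c in 1:3)
      duf$vectors[, , , c] <- pmin(pmax(duf$vectors[, , , c], -cap[c]), cap[c])
    u <- compose(u, duf)
  }
  u
}

#' One iteration of minimum-deformation template estimation
#'
#' For each visit: non-linear registration of the visit to the current
#' template (warm-started from the previous fields), then spatio-temporal
#' regularization of the whole trajectory, then removal of the mean
#' deformation (`phi_t = psi_t o inverse(mean(psi))`) so the template stays
#' centred among the visits, and finally the template update as the
#' voxel-wise mean of the visits resampled through the bias-free fields.
#'
#' @param series list of aligned `mdt_volume` visits.
#' @param template current template `mdt_volume`.
#' @param fields list of current per-visit `mdt_field` (or NULL entries).
#' @param level schedule row, as in [register_nonlinear()].
#' @param times visit times (years).
#' @param st_regularize apply the spatio-temporal constraint.
#' @param radius neighborhood radius of the regularizer.
#' @param ... forwarded to [register_nonlinear()].
#' @return list with `template`, `fields` (phi), `psi`, `mean_disp_vox`
#'   (max voxel-wise mean displacement after bias removal, in voxels) and
#'   `rms_change` (template RMS update).
#' @export
mdt_iteration <- function(series, template, fields, level, times,
                          st_regularize = TRUE, radius = 1, ...) {
  n <- length(series)
  psi <- vector("list", n)
  blur_eff <- max(level$blur, 1.2 * min(voxel_spacing(template)))
  tgtb <- smooth_gaussian(template, blur_eff)
  attr(tgtb, "preblurred") <- TRUE
  for (t in seq_len(n)) {
    srcb <- smooth_gaussian(series[[t]], blur_eff)
    attr(srcb, "preblurred") <- TRUE
    psi[[t]] <- register_nonlinear(srcb, tgtb, level,
                                   init = fields[[t]], ...)
  }
  if (st_regularize) {
    traj <- regularize(new_trajectory(psi, times), radius = radius)
    psi <- traj$fields
  }
  mbar <- mean_field(psi)
  minv <- invert_field(mbar)
  phi <- lapply(psi, compose, inner = minv)
  mres <- mean_field(phi)
  mean_disp <- max(abs(mres$vectors)) / min(voxel_spacing(template))
  warped <- lapply(seq_len(n), function(t)
    resample(series[[t]], phi[[t]], phi[[t]], order = 4))
  acc <- warped[[1]]$data
  for (t in seq(2, n)) acc <- acc + warped[[t]]$data
  new_template <- as_volume(acc / n, template$affine)
  rms_change <- sqrt(mean((new_template$data - template$data)^2))
  list(template = new_template, fields = phi, psi = psi,
       mean_disp_vox = mean_disp, rms_change = rms_change)
}

#' Longitudinal template-based bias-field correction
#'
#' Estimates, for every visit, the smooth residual intensity non-uniformity
#' between the warped visit and the current template from the log-ratio of
#' the two images over the template foreground; the per-visit fields are
#' divided by their voxel-wise geometric mean (so that no net intensity
#' change is introduced across the series), transformed back to native visit
#' space through the inverted registration field and divided out of the
#' visit images.
#'
#' @param warped list of visits resampled into template space (via psi).
#' @param template current template.
#' @param psi list of per-visit registration fields.
#' @param series native (aligned) visit volumes to correct.
#' @param fwhm smoothness of the estimated fields (mm).
#' @param fg_thresh template foreground threshold.
#' @return list with `series` (corrected volumes) and `bias` (per-visit
#'   `mdt_bias` in template space, geometric mean 1).
#' @export
longitudinal_bias_correct <- function(warped, template, psi, series,
                                      fwhm = 60, fg_thresh = 10) {
  n <- length(warped)
  fg <- template$data > fg_thresh
  if (!any(fg)) stop("longitudinal_bias_correct: empty template foreground")
  dims <- dim(template$data)
  w <- array(0, dims); w[fg] <- 1
  loga <- vector("list", n)
  for (t in seq_len(n)) {
    iw <- warped[[t]]$data
    if (any(iw[fg] <= 0)) {
      bad <- fg & (iw <= 0)
      iw[bad] <- fg_thresh   # guard isolated zeros from interpolation
    }
    r <- array(0, dims)
    r[fg] <- log(iw[fg] / pmax(template$data[fg], 1e-6))
    loga[[t]] <- smooth_masked_coarse(r, w, fwhm, template$affine)
  }
  mlog <- Reduce(`+`, loga) / n
  out_series <- vector("list", n)
  bias <- vector("list", n)
  for (t in seq_len(n)) {
    lb <- loga[[t]] - mlog
    bias[[t]] <- structure(list(values = exp(lb), affine = template$affine),
                           class = "mdt_bias")
    psi_inv <- invert_field(psi[[t]], tol = 0.05, max_iter = 12)
    bnat <- resample(as_volume(lb, template$affine), psi_inv, psi_inv,
                     order = 1)
    # divide out the estimated visit-specific non-uniformity
    out_series[[t]] <- as_volume(series[[t]]$data * exp(-bnat$data),
                                 series[[t]]$affine, series[[t]]$meta)
  }
  list(series = out_series, bias = bias)
}

#' Build the non-linear minimum deformation template of one subject
#'
#' Runs `iters_per_level` template iterations at each level of the
#' hierarchical schedule, starting from the linear template (or the visit
#' average); the template, deformation fields and bias corrections of one
#' level initialize the next. Optionally applies the spatio-temporal
#' regularization (the full longitudinal mode) and the template-based
#' longitudinal bias correction.
#'
#' @param series list of aligned, preprocessed `mdt_volume` visits.
#' @param times visit times in years.
#' @param init_template starting template (default: voxel-wise visit mean).
#' @param schedule registration schedule, see [default_schedule()].
#' @param iters_per_level template iterations per level (scalar or one
#'   entry per schedule row).
#' @param st_regularize apply the 4D regularization (FALSE gives the plain
#'   individual-template mode).
#' @param radius regularizer neighborhood radius (voxels).
#' @param bias_correct apply longitudinal bias correction each iteration.
#' @param bias_fwhm smoothness of the longitudinal bias fields (mm).
#' @param ... forwarded to [register_nonlinear()].
#' @return a `mdt_template` object: `template`, `fields` (per-visit phi),
#'   `psi`, `bias_fields`, `times`, `level_log` (per level x iteration
#'   diagnostics).
#' @export
build_nonlinear_template <- function(series, times, init_template = NULL,
                                     schedule = default_schedule(4),
                                     iters_per_level = 9,
                                     st_regularize = TRUE, radius = 1,
                                     bias_correct = FALSE, bias_fwhm = 60,
                                     ...) {
  n <- length(series)
  if (n < 2) stop("need >= 2 visits")
  schedule <- check_schedule(schedule)
  grid <- series[[1]]
  if (is.null(init_template)) {
    acc <- series[[1]]$data
    for (v in series[-1]) acc <- acc + v$data
    init_template <- as_volume(acc / n, grid$affine)
  }
  template <- init_template
  fields <- replicate(n, NULL, simplify = FALSE)
  bias <- NULL
  work <- series
  log <- list()
  ipl <- rep(iters_per_level, length.out = nrow(schedule))
  for (l in seq_len(nrow(schedule))) {
    level <- as.list(schedule[l, ])
    for (it in seq_len(ipl[l])) {
      st <- mdt_iteration(work, template, fields, level, times,
                          st_regularize = st_regularize, radius = radius,
                          ...)
      template <- st$template
      fields <- st$fields
      if (bias_correct) {
        warped <- lapply(seq_len(n), function(t)
          resample(work[[t]], st$psi[[t]], st$psi[[t]], order = 1))
        bc <- longitudinal_bias_correct(warped, template, st$psi, work,
                                        fwhm = bias_fwhm)
        work <- bc$series
        bias <- bc$bias
      }
      log[[length(log) + 1]] <- data.frame(
        level = level$step, iteration = it,
        mean_disp_vox = st$mean_disp_vox, rms_change = st$rms_change)
    }
  }
  structure(list(template = template, fields = fields, psi = st$psi,
                 bias_fields = bias, times = times,
                 level_log = do.call(rbind, log)),
            class = "mdt_template")
}

#' @exportS3Method print mdt_template
print.mdt_template <- function(x, ...) {
  cat(sprintf("<mdt_template> %d visits; levels %s mm; final mean |phi| %.3g vox\n",
              length(x$fields),
              paste(unique(x$level_log$level), collapse = "/"),
              x$level_log$mean_disp_vox[nrow(x$level_log)]))
  invisible(x)
}

#' Total non-linear transform between two time-points
#'
#' Concatenates the template-to-visit fields transitively:
#' `phi_(t1 -> t2) = phi_t1 o inverse(phi_t2)`.
#'
#' @param mdt a `mdt_template`.
#' @param t1,t2 visit indices.
#' @return a `mdt_field`.
#' @export
timepoint_transform <- function(mdt, t1, t2) {
  n <- length(mdt$fields)
  if (t1 < 1 || t1 > n || t2 < 1 || t2 > n) stop("unknown visit index")
  compose(mdt$fields[[t1]], invert_field(mdt$fields[[t2]]))
}
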