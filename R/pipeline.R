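#' Pipeline configuration
#'
#' Desk-scale defaults for the full longitudinal pipeline on phantom-sized
#' (48^3, 2.5 mm) data: preprocessing options, hierarchical schedules and
#' template iteration counts. `mode` selects the measurement strategy:
#' `"CS"` registers every visit independently to the common reference
#' (cross-sectional), `"IT"` builds the subject template without the
#' spatio-temporal constraint, `"LIT"` is the full longitudinal mode.
#'
#' @param mode `"LIT"`, `"IT"` or `"CS"`.
#' @param denoise apply patch-based denoising during preprocessing.
#' @param cs_bias_correct apply cross-sectional non-uniformity correction.
#' @param stereotaxic_dof parameter set of the per-visit stereotaxic
#'   registration.
#' @param linear_steps stereotaxic registration step sizes (mm).
#' @param template_linear_steps step sizes of the linear-template stage.
#' @param linear_iters iterations of the linear-template stage.
#' @param template_dof parameter set of the template-stage registration
#'   (`"affine12"` captures per-visit global scale; `"rigid6"` leaves scale
#'   to the non-linear stage).
#' @param schedule non-linear registration schedule (data frame).
#' @param iters_per_level template iterations per non-linear level.
#' @param st_radius neighborhood radius of the 4D regularizer (voxels).
#' @param long_bias_correct apply longitudinal bias correction (LIT/IT).
#' @param bias_fwhm smoothness (mm) of estimated bias fields.
#' @param nl_min_gain minimum correlation gain accepted by the node search.
#' @param include_linear_det include the determinants of the linear
#'   (stereotaxic / template-affine) transforms in the volume measure, so
#'   global scale changes are captured; FALSE integrates the non-linear
#'   Jacobian only.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("LIT", "IT", "CS"), denoise = TRUE,
                            cs_bias_correct = TRUE,
                            stereotaxic_dof = "similarity9",
                            linear_steps = c(8, 4),
                            template_linear_steps = c(8, 4),
                            linear_iters = 2, template_dof = "rigid6",
                            schedule = default_schedule(4),
                            iters_per_level = 3, st_radius = 1,
                            long_bias_correct = TRUE, bias_fwhm = 60,
                            include_linear_det = TRUE, nl_min_gain = 1e-4) {
  mode <- match.arg(mode)
  structure(list(mode = mode, denoise = denoise,
                 cs_bias_correct = cs_bias_correct,
                 stereotaxic_dof = stereotaxic_dof,
                 linear_steps = linear_steps,
                 template_linear_steps = template_linear_steps,
                 linear_iters = linear_iters, template_dof = template_dof,
                 schedule = schedule,
                 iters_per_level = iters_per_level, st_radius = st_radius,
                 long_bias_correct = long_bias_correct,
                 bias_fwhm = bias_fwhm,
                 include_linear_det = include_linear_det,
                 nl_min_gain = nl_min_gain),
            class = "pipeline_config")
}

foreground_mask <- function(vol, frac = 0.15) {
  thr <- frac * quantile(vol$data, 0.99, names = FALSE)
  as_volume((vol$data > thr) * 1, vol$affine)
}

#' Cross-sectional preprocessing of one longitudinal series
#'
#' Denoising (optional), non-uniformity correction (optional), linear
#' intensity normalization to the reference, stereotaxic similarity
#' registration and resampling onto the reference grid.
#'
#' @param scans list of native `mdt_volume` scans.
#' @param reference stereotaxic reference `mdt_volume`.
#' @param config a [pipeline_config()].
#' @return list with `volumes` (aligned), `xforms` (per-visit `mdt_affine`,
#'   pull-back reference -> native), `log` (per-visit parameter list).
#' @export
preprocess_series <- function(scans, reference, config = pipeline_config()) {
  out <- vector("list", length(scans))
  xf <- vector("list", length(scans))
  logs <- vector("list", length(scans))
  for (t in seq_along(scans)) {
    v <- scans[[t]]
    if (config$denoise)
      v <- denoise(v, preproc_config(denoise_search_radius = 1))
    if (config$cs_bias_correct) {
      fgm <- foreground_mask(v)
      v2 <- v
      v2$data <- pmax(v2$data, 1e-3)   # log needs positives inside mask
      bf <- estimate_bias(v2, fgm, fwhm = config$bias_fwhm, iterations = 2)
      v <- correct_bias(v, bf)
    }
    v <- normalize_intensity(v, reference)
    reg <- register_linear(v, reference, dof = config$stereotaxic_dof,
                           steps = config$linear_steps)
    out[[t]] <- resample(v, reg, reference, order = 4)
    xf[[t]] <- reg
    logs[[t]] <- list(sigma_hat = attr(v, "sigma_hat"),
                      norm = attr(v, "coef"),
                      params = attr(reg, "params"))
  }
  list(volumes = out, xforms = xf, log = logs)
}

# Independent per-visit non-linear registration to the reference.
register_to_reference <- function(vol, reference, schedule, ...) {
  u <- NULL
  for (l in seq_len(nrow(schedule)))
    u <- register_nonlinear(vol, reference, as.list(schedule[l, ]), init = u,
                            ...)
  u
}

#' Measure structure volumes of one subject
#'
#' Runs the configured measurement mode on one preprocessed subject and
#' integrates the Jacobian determinant of the total template-to-visit (or
#' reference-to-visit) transform over the structure masks. The determinant
#' of the linear (stereotaxic and template-affine) components is included so
#' global scale changes are not silently discarded.
#'
#' @param pre result of [preprocess_series()].
#' @param times visit times (years).
#' @param reference stereotaxic reference volume.
#' @param ref_masks named list of reference-space masks (used in CS mode).
#' @param subj_masks named list of subject stereotaxic masks (template
#'   modes).
#' @param config a [pipeline_config()].
#' @return list with `volumes` (data frame: visit, time, structure, volume)
#'   and `details` (mode-specific objects).
#' @export
measure_subject <- function(pre, times, reference, ref_masks, subj_masks,
                            config = pipeline_config()) {
  n <- length(pre$volumes)
  rows <- list()
  details <- list()
  lin_det <- vapply(pre$xforms, function(x) abs(det(x$matrix[1:3, 1:3])), 0)
  if (!isTRUE(config$include_linear_det)) lin_det <- rep(1, n)
  if (config$mode == "CS") {
    for (t in seq_len(n)) {
      u <- register_to_reference(pre$volumes[[t]], reference,
                                 config$schedule,
                                 min_gain = config$nl_min_gain)
      jd <- jacobian_determinant(u)
      for (nm in names(ref_masks))
        rows[[length(rows) + 1]] <- data.frame(
          visit = t, time = times[t], structure = nm,
          volume = lin_det[t] * structure_volume(ref_masks[[nm]], jd))
    }
  } else {
    lt <- build_linear_template(pre$volumes,
                                steps = config$template_linear_steps,
                                max_iter = config$linear_iters,
                                dof = config$template_dof)
    aligned <- lapply(seq_len(n), function(t)
      resample(pre$volumes[[t]], lt$affines[[t]], reference, order = 4))
    mdt <- build_nonlinear_template(
      aligned, times, init_template = lt$template,
      schedule = config$schedule, iters_per_level = config$iters_per_level,
      st_regularize = config$mode == "LIT", radius = config$st_radius,
      bias_correct = config$long_bias_correct, bias_fwhm = config$bias_fwhm,
      min_gain = config$nl_min_gain)
    aff_det <- vapply(lt$affines, function(x) abs(det(x$matrix[1:3, 1:3])), 0)
    if (!isTRUE(config$include_linear_det)) aff_det <- rep(1, n)
    for (t in seq_len(n)) {
      jd <- jacobian_determinant(mdt$fields[[t]])
      for (nm in names(subj_masks))
        rows[[length(rows) + 1]] <- data.frame(
          visit = t, time = times[t], structure = nm,
          volume = lin_det[t] * aff_det[t] *
            structure_volume(subj_masks[[nm]], jd))
    }
    details <- list(linear = lt, mdt = mdt)
  }
  list(volumes = do.call(rbind, rows), details = details)
}

#' Run the full longitudinal pipeline on a simulated dataset
#'
#' Preprocesses every subject, applies the configured measurement mode and
#' assembles the change table with per-visit volumes, VC/aVC (relative to
#' the across-visit mean) and longVC (relative to baseline).
#'
#' @param dataset a `mdt_dataset` from [simulate_scan_rescan()] or
#'   [simulate_cohort()].
#' @param config a [pipeline_config()].
#' @param modes measurement modes to run on the shared preprocessing
#'   (default: the config's mode); the change table gains a `mode` column.
#' @param keep_details keep per-subject template objects (memory-heavy).
#' @param verbose print one line per subject.
#' @return a `pipeline_result`: `change_table` (data frame with subject,
#'   group, visit, time, structure, volume, VC, aVC, longvc), `config`,
#'   `details`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         modes = config$mode, keep_details = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(dataset, "mdt_dataset"))
  reference <- dataset$reference$volume
  ref_masks <- dataset$reference$masks
  tabs <- list()
  details <- list()
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    t0 <- Sys.time()
    pre <- preprocess_series(sub$scans, reference, config)
    for (mode in modes) {
      cfg <- config
      cfg$mode <- mode
      mes <- measure_subject(pre, sub$times, reference, ref_masks,
                             sub$masks, cfg)
      tab <- mes$volumes
      tab$subject <- sub$id
      tab$group <- sub$group
      tab$mode <- mode
      tab <- do.call(rbind, lapply(split(tab, tab$structure), function(d) {
        d <- d[order(d$visit), ]
        vc <- vc_avc(d$volume)
        d$VC <- vc$VC
        d$aVC <- vc$aVC
        d$longvc <- long_vc(d$volume)
        d
      }))
      rownames(tab) <- NULL
      tabs[[length(tabs) + 1]] <- tab
      if (keep_details) details[[paste(sub$id, mode, sep = ".")]] <- mes$details
    }
    if (verbose)
      message(sprintf("%s [%s] done in %.1f s", sub$id,
                      paste(modes, collapse = "+"),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  structure(list(change_table = do.call(rbind, tabs), config = config,
                 details = details),
            class = "pipeline_result")
}

#' @exportS3Method print pipeline_result
print.pipeline_result <- function(x, ...) {
  ct <- x$change_table
  cat(sprintf("<pipeline_result> mode %s: %d subjects, %d structures\n",
              x$config$mode, length(unique(ct$subject)),
              length(unique(ct$structure))))
  agg <- stats::aggregate(aVC ~ structure + mode, ct, median)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  median aVC %-4s %-14s %.3f %%\n", agg$mode[i],
                agg$structure[i], agg$aVC[i]))
  invisible(x)
}

#' Per-structure mixed-model power report
#'
#' Fits the longitudinal mixed model to each structure of a cohort change
#' table and derives the Diggle sample size (and optional bootstrap CI),
#' mirroring a sample-size-per-arm table: annual rates per group, effect
#' size, subjects per arm.
#'
#' @param change_table a cohort change table from [run_pipeline()].
#' @param reduction treatment-effect fraction of the AD rate.
#' @param power,alpha test characteristics.
#' @param n_boot bootstrap replicates (0 = skip).
#' @param seed bootstrap seed.
#' @return data frame with one row per structure.
#' @export
power_report <- function(change_table, reduction = 0.25, power = 0.80,
                         alpha = 0.05, n_boot = 0, seed = 1) {
  out <- list()
  for (nm in unique(change_table$structure)) {
    d <- change_table[change_table$structure == nm, ]
    fit <- fit_lme(d)
    ss <- sample_size(fit, reduction = reduction, power = power,
                      alpha = alpha)
    row <- data.frame(structure = nm, rate_nc = fit$beta1,
                      rate_ad = fit$beta1 + fit$beta2,
                      beta2 = fit$beta2, se_beta2 = fit$se_beta2,
                      effect = ss$effect, n_per_arm = ss$n_per_arm,
                      sigma2 = fit$sigma2, rho = fit$rho,
                      singular = fit$singular)
    if (n_boot > 0) {
      ci <- bootstrap_ci(fit, n_boot = n_boot, seed = seed,
                         reduction = reduction, power = power,
                         alpha = alpha)$ci
      row$n_lo <- ci["n_per_arm", 1]
      row$n_hi <- ci["n_per_arm", 2]
    }
    out[[nm]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
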