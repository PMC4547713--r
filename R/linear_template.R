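#' Iterative subject-specific linear template
#'
#' Builds the linear individual template of one subject's longitudinal
#' series: starting from the voxel-wise average of the (stereotaxically
#' aligned, preprocessed) visits, each visit is affinely registered to the
#' current target, resampled with cubic interpolation and averaged. After
#' every iteration the matrix-log mean of the per-visit affines is removed so
#' the template does not drift toward any single visit (unbiasedness).
#' Iteration stops when the mean translation update drops below 0.05 mm and
#' the mean rotation update below 0.05 degrees, or at `max_iter`.
#'
#' @param series list of `mdt_volume` visits (>= 2) on a common grid.
#' @param steps hierarchical registration step sizes in mm.
#' @param max_iter maximum template iterations.
#' @param dof registration parameter set (default `affine12`).
#' @param maxit per-level similarity evaluation budget.
#' @return a `linear_template` object: `template` (`mdt_volume`), `affines`
#'   (per-visit `mdt_affine`, pull-back template -> visit), `n_iterations`,
#'   `convergence_curve` (mean parameter change per iteration).
#' @export
build_linear_template <- function(series, steps = c(32, 16, 8, 4),
                                  max_iter = 8, dof = "affine12",
                                  maxit = 300) {
  n <- length(series)
  if (n < 2) stop("build_linear_template needs at least 2 visits")
  for (v in series[-1]) if (!same_grid(series[[1]], v))
    stop("visits must share a grid")
  grid <- series[[1]]
  avg <- function(vols) {
    acc <- vols[[1]]$data
    for (v in vols[-1]) acc <- acc + v$data
    as_volume(acc / length(vols), grid$affine)
  }
  template <- avg(series)
  affines <- replicate(n, diag(4), simplify = FALSE)
  params <- replicate(n, NULL, simplify = FALSE)
  curve <- numeric(0)
  for (it in seq_len(max_iter)) {
    prev <- params
    regs <- vector("list", n)
    for (t in seq_len(n)) {
      regs[[t]] <- register_linear(series[[t]], template, dof = dof,
                                   steps = steps, init = params[[t]],
                                   maxit = maxit)
      params[[t]] <- attr(regs[[t]], "params")
    }
    # unbiasedness: remove the matrix-log mean of the visit affines
    logs <- lapply(regs, function(r) matlog4(r$matrix))
    mlog <- Reduce(`+`, logs) / n
    corr <- matexp4(-mlog)
    affines <- lapply(regs, function(r) r$matrix %*% corr)
    warped <- lapply(seq_len(n), function(t)
      resample(series[[t]], as_affine(affines[[t]]), grid, order = 4))
    template <- avg(warped)
    delta <- if (is.null(prev[[1]])) Inf else
      mean(vapply(seq_len(n), function(t)
        mean(abs(params[[t]] - prev[[t]])[1:6]), 0))
    curve <- c(curve, delta)
    if (delta < 0.05) break
  }
  structure(list(template = template,
                 affines = lapply(affines, as_affine, dof = dof),
                 n_iterations = length(curve),
                 convergence_curve = curve),
            class = "linear_template")
}

#' @exportS3Method print linear_template
print.linear_template <- function(x, ...) {
  cat(sprintf("<linear_template> %d visits, %d iterations\n",
              length(x$affines), x$n_iterations))
  invisible(x)
}
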