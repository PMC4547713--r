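#' Cross-sectional preprocessing configuration
#'
#' @param denoise_patch_radius patch radius (voxels) for the non-local-means
#'   denoiser.
#' @param denoise_search_radius search window radius (voxels).
#' @param bias_fwhm smoothing scale (mm) of the non-uniformity field estimate.
#' @param norm_lo,norm_hi anchor percentiles of the linear intensity mapping.
#' @param target_range output intensity range after normalization.
#' @param stereotaxic_dof degrees of freedom of the stereotaxic registration.
#' @return a `preproc_config` list.
#' @export
preproc_config <- function(denoise_patch_radius = 1, denoise_search_radius = 2,
                           bias_fwhm = 100, norm_lo = 1, norm_hi = 99,
                           target_range = c(0, 100),
                           stereotaxic_dof = "similarity9") {
  stopifnot(norm_lo >= 0, norm_lo < norm_hi, norm_hi <= 100,
            target_range[1] < target_range[2])
  structure(list(denoise_patch_radius = denoise_patch_radius,
                 denoise_search_radius = denoise_search_radius,
                 bias_fwhm = bias_fwhm, norm_lo = norm_lo, norm_hi = norm_hi,
                 target_range = target_range,
                 stereotaxic_dof = stereotaxic_dof),
            class = "preproc_config")
}

#' Patch-based (non-local-means) denoising
#'
#' The noise standard deviation is estimated from pseudo-residuals
#' (`sqrt(6/7) * (I - mean of 6 neighbors)`, robust MAD estimate) and patches
#' within the search window are averaged with weights
#' `exp(-max(d2 - 2 sigma^2, 0) / (2 sigma^2))` where `d2` is the mean squared
#' patch difference. A (near-)noiseless image is returned unchanged.
#'
#' @param vol a `mdt_volume` with nonnegative intensities.
#' @param cfg a [preproc_config()].
#' @return the denoised `mdt_volume`, with attribute `sigma_hat`.
#' @export
denoise <- function(vol, cfg = preproc_config()) {
  stopifnot(is_volume(vol))
  if (min(vol$data) < 0) stop("denoise expects nonnegative intensities")
  sig <- estimate_noise_sd(vol)
  rng <- diff(range(vol$data))
  if (sig < 1e-6 * max(rng, 1)) {
    attr(vol, "sigma_hat") <- sig
    return(vol)
  }
  out <- cpp_nlm(vol$data, dim(vol$data), as.integer(cfg$denoise_patch_radius),
                 as.integer(cfg$denoise_search_radius), sig, 2.0)
  res <- as_volume(array(out, dim(vol$data)), vol$affine, vol$meta)
  attr(res, "sigma_hat") <- sig
  res
}

#' Robust noise standard-deviation estimate from pseudo-residuals
#' @param vol a `mdt_volume`.
#' @return estimated Gaussian noise sd.
#' @export
estimate_noise_sd <- function(vol) {
  x <- vol$data
  d <- dim(x)
  nb <- array(0, d)
  cnt <- array(0, d)
  sh <- function(a, k) {
    # shift along axis a by k with edge replication
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[a]] + k, 1L), d[a])
    args <- idx; args[[a]] <- src
    do.call(`[`, c(list(x), args))
  }
  for (a in 1:3) for (k in c(-1L, 1L)) { nb <- nb + sh(a, k); cnt <- cnt + 1 }
  eps <- sqrt(6 / 7) * (x - nb / cnt)
  1.4826 * median(abs(eps))
}

#' Intensity non-uniformity (bias field) estimation
#'
#' A smooth multiplicative field surrogate for full histogram-sharpening
#' correction: intensities inside the mask are clustered into tissue classes
#' (k-means on log-intensity), the per-voxel residual from its class center is
#' smoothed at `fwhm` with mask-normalized convolution, exponentiated, and
#' normalized to mean 1 inside the mask.
#'
#' @param vol a `mdt_volume`, strictly positive inside the mask.
#' @param mask a binary `mdt_volume` on the same grid.
#' @param fwhm smoothing scale in mm.
#' @param k number of tissue classes (default 3).
#' @param iterations estimate / correct / re-estimate passes; the Gaussian
#'   smoothing attenuates large-scale components, so two or three passes
#'   converge to the full field.
#' @return a `mdt_bias` object: list with `values` (3D array, positive),
#'   `affine`.
#' @export
estimate_bias <- function(vol, mask, fwhm = 100, k = 3, iterations = 6) {
  stopifnot(is_volume(vol), is_volume(mask), same_grid(vol, mask))
  m <- mask$data > 0.5
  if (!any(m)) stop("estimate_bias: empty mask")
  if (min(vol$data[m]) <= 0) stop("estimate_bias: nonpositive intensity in mask")
  total <- array(1, dim(vol$data))
  work <- vol
  for (it in seq_len(iterations)) {
    b1 <- estimate_bias_once(work, m, fwhm, k)
    total <- total * b1
    work <- as_volume(work$data / b1, vol$affine)
  }
  total <- total / mean(total[m])
  return(structure(list(values = total, affine = vol$affine),
                   class = "mdt_bias"))
}

estimate_bias_once <- function(vol, m, fwhm, k) {
  lx <- log(pmax(vol$data[m], 1e-8))
  samp <- if (length(lx) > 20000) lx[seq(1, length(lx), length.out = 20000)]
          else lx
  kk <- min(k, length(unique(round(samp, 6))))
  if (kk < 2) {
    resid <- rep(0, sum(m))
    keep <- rep(TRUE, sum(m))
  } else {
    km <- with_local_seed(20830, suppressWarnings(
      kmeans(samp, centers = kk, nstart = 3, iter.max = 50)))
    ctr <- sort(as.numeric(km$centers))
    dmat <- abs(outer(lx, ctr, `-`))
    assign <- max.col(-dmat)
    resid <- lx - ctr[assign]
    # partial-volume voxels between classes carry anatomy, not bias:
    # keep only voxels close to their class center
    keep <- abs(resid) < 0.1
  }
  r <- array(0, dim(vol$data))
  w <- array(0, dim(vol$data))
  r[m][keep] <- resid[keep]
  w[m][keep] <- 1
  logb <- smooth_masked_coarse(r, w, fwhm, vol$affine)
  b <- exp(logb)
  b / mean(b[m])
}

# mask-normalized Gaussian smoothing at a large FWHM, computed on a
# 2x-decimated lattice (the result is smooth by construction) and trilinearly
# upsampled back
smooth_masked_coarse <- function(r, w, fwhm, affine, factor = 2L) {
  d <- dim(r)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  ix <- lapply(d, function(n) seq(1L, n, by = factor))
  rc <- r[ix[[1]], ix[[2]], ix[[3]]]
  wc <- w[ix[[1]], ix[[2]], ix[[3]]]
  dc <- dim(rc)
  sig <- rep(fwhm / 2.354820045, 3) / (sp * factor)
  num <- cpp_gaussian_blur(rc, dc, sig, TRUE)
  den <- cpp_gaussian_blur(wc, dc, sig, TRUE)
  out <- array(0, dc)
  ok <- den > 1e-8
  out[ok] <- num[ok] / den[ok]
  ac <- affine %*% diag(c(factor, factor, factor, 1))
  coarse <- as_volume(array(out, dc), ac)
  fine <- resample(coarse, NULL, as_volume(r, affine), order = 4)
  fine$data
}

#' Apply (divide out) a multiplicative bias field
#' @param vol a `mdt_volume`.
#' @param bias a `mdt_bias` on the same grid.
#' @return corrected `mdt_volume`.
#' @export
correct_bias <- function(vol, bias) {
  as_volume(vol$data / bias$values, vol$affine, vol$meta)
}

#' Percentile-anchored linear intensity normalization
#'
#' Finds the linear map `a*x + b` sending the (`norm_lo`, `norm_hi`)
#' percentiles of `vol` to those of `ref`, applies it, and clamps to the
#' target range.
#'
#' @param vol volume to normalize.
#' @param ref reference `mdt_volume`.
#' @param cfg a [preproc_config()].
#' @return normalized `mdt_volume` with attribute `coef` = c(a, b).
#' @export
normalize_intensity <- function(vol, ref, cfg = preproc_config()) {
  p <- c(cfg$norm_lo, cfg$norm_hi) / 100
  qv <- quantile(vol$data, p, names = FALSE)
  qr <- quantile(ref$data, p, names = FALSE)
  if (diff(qv) < 1e-12) stop("normalize_intensity: degenerate intensity spread")
  a <- diff(qr) / diff(qv)
  b <- qr[1] - a * qv[1]
  x <- a * vol$data + b
  x <- pmin(pmax(x, cfg$target_range[1]), cfg$target_range[2])
  out <- as_volume(array(x, dim(vol$data)), vol$affine, vol$meta)
  attr(out, "coef") <- c(a = a, b = b)
  out
}

## ---- linear registration ------------------------------------------------

rot3 <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Parameter vector -> 4x4 pull-back matrix about center `cen`.
# p = (tx,ty,tz, rx,ry,rz in degrees, log-scales sx,sy,sz, shears hxy,hxz,hyz)
params_to_matrix <- function(p, cen = c(0, 0, 0)) {
  p <- c(p, rep(0, 12 - length(p)))
  R <- rot3(p[4:6])
  S <- diag(exp(p[7:9]))
  H <- diag(3); H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
  A <- R %*% S %*% H
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p[1:3] + cen - A %*% cen
  M
}

n_params <- function(dof) switch(dof, rigid6 = 6L, similarity9 = 9L,
                                 affine12 = 12L,
                                 stop("unknown dof label: ", dof))

# Similarity (negative CC) of src resampled through M onto a subsampled tgt.
affine_neg_cc <- function(p, cen, srcdat, srcdims, srcaffinv, pts, tvals) {
  M <- params_to_matrix(p, cen)
  q <- cbind(pts, 1) %*% t(M)
  v <- cpp_sample_volume(srcdat, srcdims, srcaffinv, q[, 1:3, drop = FALSE], 1L)
  if (sd(v) < 1e-9) return(1)
  -suppressWarnings(stats::cor(v, tvals))
}

#' Hierarchical linear registration by local cross-correlation
#'
#' Coarse-to-fine intensity registration: at each step size the images are
#' blurred with a matched Gaussian and the requested parameter set (6, 9 or
#' 12 dof) is refined by derivative-free quadratic optimization (BOBYQA) of
#' the negative cross-correlation evaluated over a subsampled target lattice. Returns the world-to-world
#' pull-back transform, i.e. `resample(src, xform, tgt)` aligns `src` to
#' `tgt`.
#'
#' @param src,tgt `mdt_volume` objects with overlapping fields of view.
#' @param dof `"rigid6"`, `"similarity9"` or `"affine12"`.
#' @param steps hierarchical step sizes in mm (blur FWHM per level).
#' @param init optional initial parameter vector.
#' @param maxit similarity evaluations per level (BOBYQA budget).
#' @return a `mdt_affine` with attributes `params` (the parameter vector) and
#'   `converged`.
#' @export
register_linear <- function(src, tgt, dof = "similarity9",
                            steps = c(32, 16, 8, 4), init = NULL,
                            maxit = 500) {
  stopifnot(is_volume(src), is_volume(tgt))
  np <- n_params(dof)
  p <- if (is.null(init)) rep(0, np) else c(init, rep(0, np - length(init)))
  d <- dim(tgt$data)
  cen <- as.numeric(tgt$affine %*% c((d - 1) / 2, 1))[1:3]
  srcaffinv <- solve(src$affine)
  conv <- TRUE
  parscale <- c(rep(1, 3), rep(1, 3), rep(0.01, 3), rep(0.01, 3))[1:np]
  for (s in steps) {
    sb <- smooth_gaussian(src, s / 2)
    tb <- smooth_gaussian(tgt, s / 2)
    stride <- max(1L, floor(min(d) / 24))
    idx <- as.matrix(expand.grid(seq(1L, d[1], by = stride),
                                 seq(1L, d[2], by = stride),
                                 seq(1L, d[3], by = stride)))
    pts <- cbind(idx - 1, 1) %*% t(tgt$affine)
    pts <- pts[, 1:3, drop = FALSE]
    tvals <- tb$data[idx]
    fq <- function(q) affine_neg_cc(q * parscale, cen, sb$data, dim(sb$data),
                                    srcaffinv, pts, tvals)
    opt <- suppressWarnings(
      minqa::bobyqa(p / parscale, fq,
                    control = list(rhobeg = 2, rhoend = 1e-4,
                                   maxfun = maxit)))
    p <- opt$par * parscale
    conv <- conv && opt$ierr == 0
  }
  out <- as_affine(params_to_matrix(p, cen), dof)
  attr(out, "params") <- p
  attr(out, "center") <- cen
  attr(out, "converged") <- conv
  out
}

## ---- 4x4 matrix log / exp (for unbiased mean removal) -------------------

matexp4 <- function(A) {
  # scaling and squaring with a truncated series; A is small in practice
  nrm <- max(abs(A))
  k <- max(0L, ceiling(log2(max(nrm, 1e-12) / 0.25)))
  B <- A / 2^k
  X <- diag(4); term <- diag(4)
  for (m in 1:16) {
    term <- term %*% B / m
    X <- X + term
  }
  for (m in seq_len(k)) X <- X %*% X
  X
}

matlog4 <- function(M) {
  # inverse scaling and squaring: repeated square roots (Denman-Beavers),
  # then the log(I + X) series
  k <- 0L
  while (max(abs(M - diag(4))) > 0.25 && k < 30L) {
    Y <- M; Z <- diag(4)
    for (it in 1:25) {
      Yn <- 0.5 * (Y + solve(Z))
      Zn <- 0.5 * (Z + solve(Y))
      Y <- Yn; Z <- Zn
    }
    M <- Y
    k <- k + 1L
  }
  X <- M - diag(4)
  L <- matrix(0, 4, 4); P <- X
  for (m in 1:24) {
    L <- L + (-1)^(m + 1) / m * P
    P <- P %*% X
  }
  L * 2^k
}
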