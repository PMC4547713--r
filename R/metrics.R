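#' Structure volume by Jacobian-determinant integration
#'
#' Volume (mm^3) of a structure at a visit: the Jacobian determinant of the
#' template-to-visit deformation integrated over the template-space binary
#' mask, times the voxel volume.
#'
#' @param mask binary `mdt_volume` on the deformation grid.
#' @param jac_det Jacobian-determinant `mdt_volume` (see
#'   [jacobian_determinant()]), or a `mdt_field` from which it is computed.
#' @return volume in mm^3.
#' @export
structure_volume <- function(mask, jac_det) {
  if (is_field(jac_det)) jac_det <- jacobian_determinant(jac_det)
  stopifnot(is_volume(mask), is_volume(jac_det), same_grid(mask, jac_det))
  m <- mask$data > 0.5
  if (!any(m)) stop("structure_volume: empty mask")
  sum(jac_det$data[m]) * prod(voxel_spacing(mask))
}

#' Scan-rescan volume-change metrics
#'
#' Percent volume change of each visit relative to the across-visit mean,
#' `VC_t = 100 (1 - V_t / mean(V))`, and its absolute value `aVC`. Used to
#' quantify bias (VC should be centred on zero) and variability (aVC) when
#' no true change is present.
#'
#' @param volumes numeric vector of per-visit volumes (> 0, length >= 2).
#' @return data frame with columns `VC` and `aVC` (percent).
#' @export
vc_avc <- function(volumes) {
  if (length(volumes) < 2) stop("vc_avc needs >= 2 volumes")
  if (any(volumes <= 0)) stop("volumes must be positive")
  vc <- 100 * (1 - volumes / mean(volumes))
  data.frame(VC = vc, aVC = abs(vc))
}

#' Longitudinal percent volume change relative to baseline
#'
#' `longVC_t = 100 (1 - V_t / V_0)`: positive values indicate shrinkage
#' (atrophy), negative values growth (e.g. ventricles).
#'
#' @param volumes per-visit volumes.
#' @param v0 baseline volume (> 0); defaults to the first element.
#' @return numeric vector of longVC (percent).
#' @export
long_vc <- function(volumes, v0 = volumes[1]) {
  if (v0 <= 0) stop("baseline volume must be positive")
  100 * (1 - volumes / v0)
}
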