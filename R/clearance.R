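# Exact 1D squared-distance relaxation: for each line along `axis`,
# out[i] = min_j (f[j] + ((i-j)*h)^2), computed by a vectorized min-plus
# reduction. Applying it per axis in sequence yields the exact Euclidean
# squared distance transform (the per-axis minimizations decouple).
edt_pass <- function(f, axis, h) {
  d <- dim(f)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(f, perm), d[axis])
  n <- nrow(m)
  idx <- seq_len(n)
  out <- m
  for (j in idx) {
    cand <- outer(((idx - j) * h)^2, m[j, ], "+")
    out <- pmin(out, cand)
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Euclidean distance from parenchyma to the nearest CSF compartment
#'
#' Computes the anisotropy-aware Euclidean distance transform of the CSF
#' set, measured between voxel centers (a face neighbor of a CSF voxel is
#' one spacing away). The CSF set is the union of the ventricles and
#' everything outside the brain (a subarachnoid-space proxy), optionally
#' extended by the PVS segmentation under the assumption of rapid
#' advective exchange between PVS and CSF.
#'
#' @param ventricle_mask ventricle \code{\link{seg_mask}}.
#' @param brain_mask brain \code{seg_mask}; all voxels outside it count as
#'   CSF.
#' @param pvs_mask optional PVS \code{seg_mask} to include in the CSF set.
#' @return a \code{distance_map}: an \code{\link{image_volume}} of
#'   distances in mm (0 on CSF voxels), with attributes \code{with_pvs}
#'   (flag) and \code{parenchyma_mask} (brain minus CSF, the region over
#'   which clearance statistics are meaningful).
#' @export
distance_to_csf <- function(ventricle_mask, brain_mask, pvs_mask = NULL) {
  check_same_geometry(ventricle_mask, brain_mask)
  csf <- unclass(ventricle_mask) | !unclass(brain_mask)
  if (!is.null(pvs_mask)) {
    check_same_geometry(ventricle_mask, pvs_mask)
    csf <- csf | unclass(pvs_mask)
  }
  if (!any(csf)) stop("CSF set is empty")
  sp <- voxel_spacing(brain_mask)
  f <- array(ifelse(csf, 0, Inf), dim(csf))
  for (ax in 1:3) f <- edt_pass(f, ax, sp[ax])
  out <- image_volume(sqrt(f), sp)
  attr(out, "with_pvs") <- !is.null(pvs_mask)
  attr(out, "parenchyma_mask") <- seg_mask(unclass(brain_mask) & !csf, sp)
  class(out) <- c("distance_map", class(out))
  out
}

#' Summary statistics of the minimum clearance distance over a region
#'
#' @param dmap a distance map from \code{\link{distance_to_csf}}.
#' @param region_mask region over which to summarize; defaults to the
#'   map's parenchyma mask.
#' @param breaks histogram bin count (default 50, spanning 0 to the region
#'   maximum) or an explicit vector of bin edges.
#' @return list with \code{mean}, \code{sd}, \code{max} (mm), \code{n}
#'   voxels, and \code{histogram} (counts + edges).
#' @export
mcd_stats <- function(dmap, region_mask = NULL, breaks = 50L) {
  if (is.null(region_mask)) region_mask <- attr(dmap, "parenchyma_mask")
  check_same_geometry(dmap, region_mask)
  if (!any(region_mask)) stop("empty region mask")
  v <- dmap[unclass(region_mask)]
  if (length(breaks) == 1L)
    breaks <- seq(0, max(v) + .Machine$double.eps, length.out = breaks + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(mean = mean(v), sd = stats::sd(v), max = max(v), n = length(v),
       histogram = list(counts = h$counts, edges = h$breaks))
}

#' Diffusive clearance time scale
#'
#' \eqn{\tau_d = L^2 / D^*}: the time for a solute with effective
#' parenchymal diffusivity \eqn{D^*} to diffuse the clearance distance
#' \eqn{L}.
#'
#' @param L clearance distance in mm (scalar or vector).
#' @param D_star effective diffusivity in um^2/s (> 0).
#' @return time scale in seconds.
#' @export
diffusive_time <- function(L, D_star) {
  if (any(L < 0)) stop("L must be non-negative")
  if (D_star <= 0) stop("D_star must be positive")
  (L * 1000)^2 / D_star
}

#' Advective clearance time scale
#'
#' \eqn{\tau_a = L / u}: the time to traverse the clearance distance
#' \eqn{L} at interstitial velocity \eqn{u}.
#'
#' @param L clearance distance in mm (scalar or vector).
#' @param u interstitial velocity magnitude in um/s (> 0).
#' @return time scale in seconds.
#' @export
advective_time <- function(L, u) {
  if (any(L < 0)) stop("L must be non-negative")
  if (u <= 0) stop("u must be positive")
  (L * 1000) / u
}

#' Voxel-averaging correction to the minimum clearance distance
#'
#' A vessel thinner than the voxel grid lying at the shared vertex of four
#' in-plane voxels enhances all four, so the segmentation places CSF at
#' those voxel centers and the in-plane clearance distance is
#' underestimated by the center-to-vertex distance minus the vessel
#' radius: \eqn{\sqrt{2}\,(s/2) - d/2} for spacing \eqn{s} and vessel
#' diameter \eqn{d}.
#'
#' @param vessel_diameter vessel diameter in um (must be < 2 * spacing).
#' @param spacing in-plane voxel size in um.
#' @return maximal underestimated distance in um (clamped at 0 with a
#'   warning if the vessel already reaches the voxel centers).
#' @export
mcd_voxel_correction <- function(vessel_diameter, spacing) {
  if (vessel_diameter >= 2 * spacing)
    stop("correction applies to vessels thinner than two voxels")
  out <- sqrt(2) * spacing / 2 - vessel_diameter / 2
  if (out < 0) {
    warning("vessel reaches beyond the voxel centers; clamping correction to 0")
    out <- 0
  }
  out
}

#' Fixation-shrinkage corrections to length and time scales
#'
#' Formalin fixation shrinks brain tissue by a volume fraction \code{f};
#' restoring in vivo geometry scales volume by \eqn{1/(1-f)}, lengths (and
#' hence clearance distances) by the cube root of that, and diffusive time
#' scales by its square.
#'
#' @param volume_shrinkage_fraction fixation volume loss \code{f} in
#'   [0, 1).
#' @return list of fractional increases: \code{volume}, \code{linear}
#'   (MCD), \code{timescale}.
#' @export
shrinkage_correction <- function(volume_shrinkage_fraction) {
  f <- volume_shrinkage_fraction
  if (f < 0 || f >= 1) stop("shrinkage fraction must lie in [0, 1)")
  vol <- 1 / (1 - f) - 1
  lin <- (1 + vol)^(1 / 3) - 1
  list(volume = vol, linear = lin, timescale = (1 + lin)^2 - 1)
}

#' Format a duration in seconds at a natural magnitude
#'
#' @param seconds numeric duration(s).
#' @return character like \code{"3.57 min"} or \code{"2.74 h"}.
#' @export
format_duration <- function(seconds) {
  vapply(seconds, function(s) {
    if (!is.finite(s)) return(as.character(s))
    if (s < 120) sprintf("%.3g s", s)
    else if (s < 7200) sprintf("%.3g min", s / 60)
    else sprintf("%.3g h", s / 3600)
  }, character(1))
}
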