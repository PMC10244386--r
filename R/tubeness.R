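#' Configuration for tubeness computation and threshold calibration
#'
#' @param gaussian_sigma physical smoothing scale in mm (default 0.04, i.e.
#'   one voxel at the native resolution — tuned to near-voxel-width tubes).
#' @param interior_quantile cumulative level used for naive-control
#'   threshold calibration (default 0.95).
#' @param surface_shell_thickness thickness, in voxels, of the brain-surface
#'   shell that gets its own (higher) threshold (default 3).
#' @param reference_peak target intensity for histogram-peak alignment
#'   (default 100).
#' @param derivative how the Hessian is obtained: \code{"central"} (Gaussian
#'   smoothing followed by spacing-aware central finite differences, the
#'   default) or \code{"gaussian"} (direct Gaussian-derivative convolution).
#' @return a \code{tubeness_config} list.
#' @export
tubeness_config <- function(gaussian_sigma = 0.04, interior_quantile = 0.95,
                            surface_shell_thickness = 3L,
                            reference_peak = 100,
                            derivative = c("central", "gaussian")) {
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be positive")
  if (interior_quantile <= 0 || interior_quantile >= 1)
    stop("interior_quantile must lie in (0, 1)")
  if (surface_shell_thickness < 1) stop("surface_shell_thickness must be >= 1")
  structure(list(gaussian_sigma = gaussian_sigma,
                 interior_quantile = interior_quantile,
                 surface_shell_thickness = as.integer(surface_shell_thickness),
                 reference_peak = reference_peak,
                 derivative = match.arg(derivative)),
            class = "tubeness_config")
}

# --- intensity peak alignment ----------------------------------------------

#' Mode of an intensity sample by histogram peak
#'
#' 256 equal-width bins spanning the 0.5-99.5 percentile range; the mode is
#' the center of the tallest bin (robust to the long bright tail contributed
#' by CSF and tube voxels).
#'
#' @param values numeric vector of intensities.
#' @param bins number of histogram bins (default 256).
#' @return the modal intensity (bin center).
#' @export
intensity_mode <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite intensities")
  r <- stats::quantile(values, c(0.005, 0.995), names = FALSE)
  if (diff(r) <= 0) stop("degenerate (constant) intensity distribution")
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  h <- findInterval(values, edges, rightmost.closed = TRUE)
  h <- tabulate(h[h >= 1L & h <= bins], nbins = bins)
  k <- which.max(h)
  (edges[k] + edges[k + 1L]) / 2
}

#' Align the within-brain intensity peak to a reference level
#'
#' Contrast infusion shifts a brain's whole intensity distribution relative
#' to unenhanced controls; thresholds calibrated on controls are only
#' transferable after the distribution peaks (parenchymal modes) are
#' aligned. This rescales the volume linearly so its within-brain modal
#' intensity equals \code{reference_peak}.
#'
#' @param volume an \code{\link{image_volume}}.
#' @param brain_mask brain \code{\link{seg_mask}}.
#' @param reference_peak target modal intensity.
#' @return the rescaled \code{image_volume}; the multiplier is attached as
#'   attribute \code{scale_factor}.
#' @export
remap_intensity <- function(volume, brain_mask, reference_peak) {
  check_same_geometry(volume, brain_mask)
  if (!any(brain_mask)) stop("brain_mask is empty")
  m <- intensity_mode(volume[brain_mask])
  if (!is.finite(m) || m == 0) stop("within-brain intensity mode is degenerate")
  s <- reference_peak / m
  out <- image_volume(unclass(volume) * s, voxel_spacing(volume))
  attr(out, "scale_factor") <- s
  out
}

# --- separable Gaussian filtering and derivatives ---------------------------

# n x n convolution matrix along one axis with replicate-edge padding.
# `kernel` is indexed by integer offsets -r..r.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (t in -r:r) {
    j <- pmin(pmax(seq_len(n) + t, 1L), n)
    S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + kernel[t + r + 1L]
  }
  S
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(-r:r, sd = sigma_vox)
  w / sum(w)
}

# Apply matrix M (n x n) along `axis` of a 3D array.
apply_along_axis <- function(a, M, axis) {
  d <- dim(a)
  if (axis == 1L) {
    array(M %*% matrix(a, d[1]), d)
  } else if (axis == 2L) {
    ap <- aperm(a, c(2L, 1L, 3L))
    aperm(array(M %*% matrix(ap, d[2]), d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  } else {
    ap <- aperm(a, c(3L, 1L, 2L))
    aperm(array(M %*% matrix(ap, d[3]), d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  }
}

#' Gaussian-smooth a volume at a physical scale
#'
#' Separable Gaussian filtering with the standard deviation given in mm and
#' converted to voxels per axis, so anisotropic spacings smooth correctly.
#' Edges are handled by replicate padding.
#'
#' @param volume an \code{\link{image_volume}}.
#' @param sigma_mm smoothing SD in mm.
#' @return smoothed \code{image_volume}.
#' @export
gaussian_smooth <- function(volume, sigma_mm) {
  sp <- voxel_spacing(volume)
  a <- unclass(volume)
  for (ax in 1:3) {
    M <- conv_matrix(dim(a)[ax], gauss_kernel(sigma_mm / sp[ax]))
    a <- apply_along_axis(a, M, ax)
  }
  image_volume(a, sp)
}

# Derivative convolution matrices for the "gaussian" mode: sampled Gaussian
# derivatives with moment corrections so that constants map to 0 and the
# response to x (resp. x^2/2) is exactly 1.
gauss_deriv_matrix <- function(n, sigma_vox, h, order) {
  r <- max(2L, ceiling(4 * sigma_vox))
  x <- (-r:r) * h
  s <- sigma_vox * h
  phi <- exp(-x^2 / (2 * s^2)) / (sqrt(2 * pi) * s)
  w <- if (order == 1L) (-x / s^2) * phi else ((x^2 - s^2) / s^4) * phi
  w <- w * h
  w <- w - mean(w)
  mom <- if (order == 1L) sum(w * x) else sum(w * x^2 / 2)
  conv_matrix(n, w / mom)
}

# Hessian components of a (smoothed) volume by spacing-aware central
# differences with replicate-edge padding.
hessian_central <- function(a, sp) {
  d2 <- function(ax) {
    (shift_array(a, ax, 1L) - 2 * a + shift_array(a, ax, -1L)) / sp[ax]^2
  }
  d1 <- function(b, ax) {
    (shift_array(b, ax, 1L) - shift_array(b, ax, -1L)) / (2 * sp[ax])
  }
  list(h11 = d2(1L), h22 = d2(2L), h33 = d2(3L),
       h12 = d1(d1(a, 1L), 2L), h13 = d1(d1(a, 1L), 3L),
       h23 = d1(d1(a, 2L), 3L))
}

hessian_gaussian <- function(a, sp, sigma_mm) {
  d <- dim(a)
  G0 <- lapply(1:3, function(ax) conv_matrix(d[ax], gauss_kernel(sigma_mm / sp[ax])))
  G1 <- lapply(1:3, function(ax) gauss_deriv_matrix(d[ax], sigma_mm / sp[ax], sp[ax], 1L))
  G2 <- lapply(1:3, function(ax) gauss_deriv_matrix(d[ax], sigma_mm / sp[ax], sp[ax], 2L))
  comp <- function(ord) {
    out <- a
    for (ax in 1:3) {
      M <- switch(ord[ax] + 1L, G0[[ax]], G1[[ax]], G2[[ax]])
      out <- apply_along_axis(out, M, ax)
    }
    out
  }
  list(h11 = comp(c(2L, 0L, 0L)), h22 = comp(c(0L, 2L, 0L)),
       h33 = comp(c(0L, 0L, 2L)), h12 = comp(c(1L, 1L, 0L)),
       h13 = comp(c(1L, 0L, 1L)), h23 = comp(c(0L, 1L, 1L)))
}

# Vectorized eigenvalues of symmetric 3x3 matrices given component arrays;
# returns l1 >= l2 >= l3 (trigonometric closed form for symmetric matrices).
eig_sym3 <- function(h11, h22, h33, h12, h13, h23) {
  q <- (h11 + h22 + h33) / 3
  p1 <- h12^2 + h13^2 + h23^2
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  psafe <- ifelse(p > 0, p, 1)
  b11 <- (h11 - q) / psafe; b22 <- (h22 - q) / psafe; b33 <- (h33 - q) / psafe
  b12 <- h12 / psafe; b13 <- h13 / psafe; b23 <- h23 / psafe
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  zero <- p2 == 0
  if (any(zero)) { l1[zero] <- q[zero]; l2[zero] <- q[zero]; l3[zero] <- q[zero] }
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Compute the Hessian-based tubeness of a volume
#'
#' Smooths the intensity field at the configured physical scale, forms the
#' 3x3 Hessian of second spatial derivatives per voxel, extracts its (real)
#' eigenvalues sorted \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}, and
#' scores each voxel \eqn{\sqrt{\lambda_2 \lambda_3}} when both are
#' negative, else 0. Bright tubular structures have near-zero curvature
#' along the tube axis and strongly negative curvature across it, so the
#' geometric mean of the two most negative eigenvalues is large on tube
#' axes, zero on dark tubes and flat regions.
#'
#' @param volume an \code{\link{image_volume}}.
#' @param config a \code{\link{tubeness_config}}; \code{gaussian_sigma} must
#'   be at least the smallest voxel spacing.
#' @return an \code{image_volume} of non-negative tubeness scores, with the
#'   config attached as attribute \code{config} and the per-axis voxel
#'   width of the edge band affected by replicate padding as attribute
#'   \code{edge_voxels}.
#' @export
compute_tubeness <- function(volume, config = tubeness_config()) {
  sp <- voxel_spacing(volume)
  if (config$gaussian_sigma < min(sp) - 1e-12)
    stop("gaussian_sigma must be at least the smallest voxel spacing")
  a <- unclass(volume)
  H <- if (config$derivative == "central") {
    hessian_central(unclass(gaussian_smooth(volume, config$gaussian_sigma)), sp)
  } else {
    hessian_gaussian(a, sp, config$gaussian_sigma)
  }
  ev <- eig_sym3(H$h11, H$h22, H$h33, H$h12, H$h13, H$h23)
  tub <- ifelse(ev$l2 < 0 & ev$l3 < 0, sqrt(pmax(ev$l2 * ev$l3, 0)), 0)
  out <- image_volume(array(tub, dim(a)), sp)
  attr(out, "config") <- config
  attr(out, "edge_voxels") <- ceiling(4 * config$gaussian_sigma / sp) + 1L
  out
}

# --- regions, calibration, segmentation ------------------------------------

#' Partition the brain into a surface shell and an interior region
#'
#' The shell consists of brain voxels within \code{thickness} voxels
#' (Chebyshev distance, i.e. repeated 26-connected erosion) of the
#' brain-mask boundary. The brain/background interface produces high
#' tubeness even without contrast, so the shell gets its own calibrated
#' threshold.
#'
#' @param brain_mask brain \code{\link{seg_mask}}.
#' @param thickness shell thickness in voxels.
#' @return named list of \code{seg_mask}s: \code{interior} and
#'   \code{surface}, which partition the brain.
#' @export
brain_regions <- function(brain_mask, thickness = 3L) {
  core <- unclass(brain_mask)
  for (i in seq_len(thickness)) core <- erode_once(core, 26L)
  sp <- voxel_spacing(brain_mask)
  list(interior = seg_mask(core, sp),
       surface = seg_mask(unclass(brain_mask) & !core, sp))
}

#' Calibrate per-region tubeness thresholds from naive controls
#'
#' For each region, the threshold is the mean over the naive volumes of
#' that volume's \code{quantile}-level tubeness within the region — a value
#' exceeding the tubeness of (on average) a fraction \code{quantile} of
#' unenhanced voxels, so that segmentation excludes background tubeness not
#' associated with contrast uptake.
#'
#' @param naive_tubeness list of tubeness volumes from naive controls
#'   (outputs of \code{\link{compute_tubeness}}).
#' @param region_masks named list of region \code{seg_mask}s (e.g. from
#'   \code{\link{brain_regions}}).
#' @param quantile cumulative level (default 0.95).
#' @return named numeric vector of thresholds, one per region.
#' @export
calibrate_threshold <- function(naive_tubeness, region_masks, quantile = 0.95) {
  if (!length(naive_tubeness)) stop("at least one naive tubeness volume is required")
  if (is.null(names(region_masks)) || !length(region_masks))
    stop("region_masks must be a non-empty named list")
  vapply(region_masks, function(reg) {
    if (!any(reg)) stop("empty region mask")
    mean(vapply(naive_tubeness, function(tv) {
      check_same_geometry(tv, reg)
      stats::quantile(tv[reg], quantile, names = FALSE)
    }, numeric(1)))
  }, numeric(1))
}

#' Segment perivascular spaces by region-thresholded tubeness
#'
#' A voxel is segmented as PVS iff its tubeness exceeds the threshold of
#' the region containing it, it lies inside the brain, and outside the
#' ventricles and every exclusion mask (e.g. a cerebellum mask whose
#' internal boundaries would otherwise contaminate the segmentation).
#'
#' @param tubeness tubeness volume from \code{\link{compute_tubeness}}.
#' @param thresholds named numeric vector of per-region thresholds.
#' @param region_masks named list of region masks matching
#'   \code{thresholds}.
#' @param brain_mask,ventricle_mask \code{\link{seg_mask}}s.
#' @param exclusion_masks optional list of additional masks to exclude.
#' @return the PVS \code{\link{seg_mask}}.
#' @export
segment_pvs <- function(tubeness, thresholds, region_masks, brain_mask,
                        ventricle_mask = NULL, exclusion_masks = list()) {
  if (!all(names(thresholds) %in% names(region_masks)))
    stop("every threshold needs a matching region mask")
  check_same_geometry(tubeness, brain_mask)
  seg <- array(FALSE, dim(tubeness))
  for (nm in names(thresholds)) {
    reg <- region_masks[[nm]]
    check_same_geometry(tubeness, reg)
    seg <- seg | (unclass(reg) & unclass(tubeness) > thresholds[[nm]])
  }
  seg <- seg & unclass(brain_mask)
  if (!is.null(ventricle_mask)) {
    check_same_geometry(tubeness, ventricle_mask)
    seg <- seg & !unclass(ventricle_mask)
  }
  for (ex in exclusion_masks) {
    check_same_geometry(tubeness, ex)
    seg <- seg & !unclass(ex)
  }
  seg_mask(seg, voxel_spacing(tubeness))
}

#' Percent of a volume of interest segmented as PVS
#'
#' @param pvs_mask PVS \code{\link{seg_mask}}.
#' @param voi_mask non-empty volume-of-interest \code{seg_mask}.
#' @return percentage \code{100 * |pvs & voi| / |voi|}.
#' @export
percent_volume <- function(pvs_mask, voi_mask) {
  check_same_geometry(pvs_mask, voi_mask)
  n <- sum(voi_mask)
  if (n == 0) stop("empty volume of interest")
  100 * sum(pvs_mask & voi_mask) / n
}
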