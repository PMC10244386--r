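#' Construct a 3D image volume with physical voxel spacing
#'
#' The basic container for all volumetric data in pvsnet: a numeric 3D array
#' carrying the physical voxel size (mm) on each axis. Voxel centers are at
#' physical position \code{(index - 0.5) * spacing} on each axis (1-based
#' array indices), so the first voxel center sits half a voxel from the
#' volume origin.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric vector of length 3, voxel size in mm per axis
#'   (default 0.04 mm isotropic, the native resolution of the high-field
#'   ex vivo acquisitions this package targets).
#' @return an \code{image_volume}: the array with a \code{spacing} attribute.
#' @export
image_volume <- function(data, spacing = c(0.04, 0.04, 0.04)) {
  if (length(dim(data)) != 3L)
    stop("image_volume requires a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all voxel spacings must be positive")
  structure(data, spacing = spacing, class = c("image_volume", class(data)))
}

#' Construct a binary segmentation mask sharing a volume's geometry
#'
#' @param data logical 3D array.
#' @param spacing voxel size in mm per axis.
#' @return a \code{seg_mask} logical array with a \code{spacing} attribute.
#' @export
seg_mask <- function(data, spacing = c(0.04, 0.04, 0.04)) {
  if (length(dim(data)) != 3L)
    stop("seg_mask requires a 3D array")
  storage.mode(data) <- "logical"
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("all voxel spacings must be positive")
  structure(data, spacing = spacing, class = c("seg_mask", class(data)))
}

#' Voxel spacing of a volume or mask
#' @param x an \code{image_volume} or \code{seg_mask}.
#' @return numeric length-3 vector (mm).
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object carries no spacing attribute")
  sp
}

# Error unless all objects share grid shape and spacing.
check_same_geometry <- function(...) {
  objs <- list(...)
  d0 <- dim(objs[[1L]]); s0 <- voxel_spacing(objs[[1L]])
  for (o in objs[-1L]) {
    if (!identical(dim(o), d0))
      stop("geometry mismatch: grid shapes differ (", paste(d0, collapse = "x"),
           " vs ", paste(dim(o), collapse = "x"), ")")
    if (max(abs(voxel_spacing(o) - s0)) > 1e-9)
      stop("geometry mismatch: voxel spacings differ")
  }
  invisible(TRUE)
}

#' Physical coordinates of voxel centers
#'
#' @param shape integer length-3 grid shape.
#' @param spacing numeric length-3 voxel size (mm).
#' @param axis which axis (1..3).
#' @return numeric vector of center coordinates (mm) along \code{axis}.
#' @export
voxel_centers <- function(shape, spacing, axis) {
  (seq_len(shape[axis]) - 0.5) * spacing[axis]
}

# Shift an array along an axis by `by` voxels, replicating the edge value
# (clamped indices). Used for finite differences and morphology.
shift_array <- function(a, axis, by, fill = NULL) {
  n <- dim(a)[axis]
  idx <- seq_len(n) + by
  if (is.null(fill)) {
    idx <- pmin(pmax(idx, 1L), n)
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  } else {
    ok <- idx >= 1L & idx <= n
    out <- array(fill, dim(a))
    src <- idx[ok]; dst <- seq_len(n)[ok]
    if (length(src)) {
      switch(axis,
             out[dst, , ] <- a[src, , , drop = FALSE],
             out[, dst, ] <- a[, src, , drop = FALSE],
             out[, , dst] <- a[, , src, drop = FALSE])
    }
    out
  }
}

# Neighborhood offsets for 6/18/26 connectivity as an integer matrix (k x 3).
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  m <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = m == 1,
                 "18" = m >= 1 & m <= 2,
                 "26" = m >= 1)
  unname(g[keep, , drop = FALSE])
}

# One binary dilation step by the structuring element of the given
# connectivity (shift-and-OR over neighborhood offsets).
dilate_once <- function(mask, connectivity = 26L) {
  offs <- connectivity_offsets(connectivity)
  out <- mask
  for (r in seq_len(nrow(offs))) {
    sh <- mask
    for (ax in 1:3) {
      if (offs[r, ax] != 0L) sh <- shift_array(sh, ax, offs[r, ax], fill = FALSE)
    }
    out <- out | sh
  }
  out
}

erode_once <- function(mask, connectivity = 26L) {
  !dilate_once(!mask, connectivity)
}

#' Read a NIfTI file as an image volume
#' @param path path to a .nii or .nii.gz file.
#' @return an \code{image_volume} with spacing from the header (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]), RNifti::pixdim(img)[1:3])
}

#' Write an image volume or mask to NIfTI
#' @param x an \code{image_volume} or \code{seg_mask}.
#' @param path output path (.nii or .nii.gz); spacing goes into the header.
#' @export
write_volume <- function(x, path) {
  a <- array(as.numeric(x), dim(x))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- voxel_spacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a binary mask
#' @param path path to a .nii or .nii.gz file; voxels > 0.5 become TRUE.
#' @return a \code{seg_mask}.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  seg_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]), RNifti::pixdim(img)[1:3])
}
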