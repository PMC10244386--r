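#' Partial maximum intensity projection (pMIP)
#'
#' Projects the maximum intensity through a slab of \code{thickness}
#' consecutive slices perpendicular to \code{axis}, the standard way of
#' making near-voxel-width bright tubular structures visible without letting
#' the bright ventricles occlude them (as a full-volume MIP would).
#'
#' @param volume an \code{\link{image_volume}}.
#' @param axis array axis to project along (1..3), or one of
#'   \code{"coronal"}, \code{"sagittal"}, \code{"transverse"} mapped to axes
#'   1/2/3 under an RAS-like axis ordering.
#' @param start first slice of the projection window (1-based).
#' @param thickness number of slices in the window (default 30).
#' @return a 2D matrix of per-pixel window maxima, with the in-plane
#'   spacings attached as attribute \code{spacing}.
#' @export
partial_mip <- function(volume, axis, start = 1L, thickness = 30L) {
  axis <- resolve_axis(axis)
  n <- dim(volume)[axis]
  start <- as.integer(start); thickness <- as.integer(thickness)
  if (thickness < 1L) stop("thickness must be >= 1")
  if (start < 1L || start + thickness - 1L > n)
    stop("projection window [", start, ", ", start + thickness - 1L,
         "] outside axis extent ", n)
  sl <- function(i) switch(axis,
                           volume[i, , , drop = TRUE],
                           volume[, i, , drop = TRUE],
                           volume[, , i, drop = TRUE])
  out <- sl(start)
  for (i in seq_len(thickness - 1L)) out <- pmax(out, sl(start + i))
  attr(out, "spacing") <- voxel_spacing(volume)[-axis]
  out
}

#' Shifting maximum intensity projection (spMIP) stack
#'
#' Slides the pMIP window one slice at a time along \code{axis}, producing
#' \code{extent - thickness + 1} frames; frame \code{i} equals
#' \code{partial_mip(volume, axis, start = i, thickness)}. Consecutive
#' frames overlap in all but one slice, so continuous tubular segments can
#' be followed through the volume.
#'
#' @inheritParams partial_mip
#' @return list of 2D projection matrices.
#' @export
shifting_mip <- function(volume, axis, thickness = 30L) {
  axis <- resolve_axis(axis)
  n <- dim(volume)[axis]
  thickness <- as.integer(thickness)
  if (n < thickness)
    stop("axis extent ", n, " is smaller than window thickness ", thickness)
  lapply(seq_len(n - thickness + 1L),
         function(i) partial_mip(volume, axis, i, thickness))
}

resolve_axis <- function(axis) {
  if (is.character(axis)) {
    axis <- match.arg(axis, c("coronal", "sagittal", "transverse"))
    axis <- match(axis, c("coronal", "sagittal", "transverse"))
  }
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2, 3 or an anatomical plane name")
  axis
}

#' Write a projection stack as numbered PNG frames with a JSON manifest
#'
#' Frames are rescaled to a common 0..1 display range over the whole stack.
#'
#' @param frames list of 2D matrices (from \code{\link{shifting_mip}}) or a
#'   single matrix.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the manifest as a list (also written to
#'   \code{manifest.json}: frame files and window start indices).
#' @export
write_mip_stack <- function(frames, dir, prefix = "mip") {
  if (is.matrix(frames)) frames <- list(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rng <- range(unlist(lapply(frames, range)))
  span <- if (diff(rng) > 0) diff(rng) else 1
  files <- character(length(frames))
  for (i in seq_along(frames)) {
    files[i] <- sprintf("%s_%04d.png", prefix, i)
    img <- (frames[[i]] - rng[1]) / span
    # write with first array axis horizontal, second vertical (top row = y max)
    png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE],
                  file.path(dir, files[i]))
  }
  manifest <- list(frames = files, start_index = seq_along(frames),
                   display_range = rng)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
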