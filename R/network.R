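#' Configuration for region growing and ventricle dilation
#'
#' @param connectivity voxel neighborhood: 6 (faces), 18 (faces + edges) or
#'   26 (full cube, the default — consistent with counting the three-voxel
#'   diagonal as "within reach" of the ventricular surface).
#' @param max_iterations growth iteration cap (default 100).
#' @param margin_voxels dilation radius applied to the ventricle seed before
#'   growing (default 3; at 0.04 mm isotropic spacing the farthest captured
#'   corner is sqrt(3) * 0.12 mm ~ 0.208 mm from the ventricular surface).
#' @return a \code{grow_config} list.
#' @export
grow_config <- function(connectivity = 26L, max_iterations = 100L,
                        margin_voxels = 3L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (margin_voxels < 0L) stop("margin_voxels must be >= 0")
  structure(list(connectivity = connectivity,
                 max_iterations = as.integer(max_iterations),
                 margin_voxels = as.integer(margin_voxels)),
            class = "grow_config")
}

#' Morphologically dilate a binary mask
#'
#' \code{margin_voxels} iterations of dilation by the structuring element
#' implied by \code{connectivity}; the input is always a subset of the
#' output.
#'
#' @param mask a \code{\link{seg_mask}}.
#' @param margin_voxels number of dilation iterations (0 = identity).
#' @param connectivity 6, 18 or 26.
#' @return the dilated \code{seg_mask}.
#' @export
dilate_mask <- function(mask, margin_voxels = 3L, connectivity = 26L) {
  m <- unclass(mask)
  for (i in seq_len(margin_voxels)) m <- dilate_once(m, connectivity)
  seg_mask(m, voxel_spacing(mask))
}

# Layered region growing on voxel index lists. Returns the visited logical
# array plus the per-iteration lists of newly added linear indices.
grow_layers <- function(seed_mask, candidate_mask, connectivity, max_iterations) {
  d <- dim(seed_mask)
  offs <- connectivity_offsets(connectivity)
  visited <- unclass(seed_mask)
  cand <- unclass(candidate_mask)
  frontier <- which(visited)
  layers <- vector("list", max_iterations)
  nlayers <- 0L
  for (it in seq_len(max_iterations)) {
    if (!length(frontier)) break
    fi <- arrayInd(frontier, d)
    nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
      cbind(fi[, 1L] + offs[r, 1L], fi[, 2L] + offs[r, 2L],
            fi[, 3L] + offs[r, 3L])))
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    nb <- nb[ok, , drop = FALSE]
    lin <- unique(nb[, 1L] + (nb[, 2L] - 1L) * d[1L] +
                    (nb[, 3L] - 1L) * d[1L] * d[2L])
    lin <- lin[cand[lin] & !visited[lin]]
    if (!length(lin)) break
    visited[lin] <- TRUE
    nlayers <- nlayers + 1L
    layers[[nlayers]] <- lin
    frontier <- lin
  }
  list(visited = visited, layers = layers[seq_len(nlayers)])
}

#' Grow a seed region into a candidate mask
#'
#' Iteratively adds candidate voxels adjacent (per the configured
#' connectivity) to the growing set, for at most
#' \code{config$max_iterations} iterations or until no voxel is added.
#'
#' @param seed_mask starting \code{\link{seg_mask}} (e.g. dilated
#'   ventricles).
#' @param candidate_mask mask of voxels eligible for capture (e.g. the PVS
#'   segmentation).
#' @param config a \code{\link{grow_config}}.
#' @return the captured \code{seg_mask}: grown set minus the original seed
#'   (always a subset of \code{candidate_mask}).
#' @export
region_grow <- function(seed_mask, candidate_mask, config = grow_config()) {
  check_same_geometry(seed_mask, candidate_mask)
  if (!any(seed_mask)) {
    warning("empty seed mask: nothing to grow")
    return(seg_mask(array(FALSE, dim(seed_mask)), voxel_spacing(seed_mask)))
  }
  g <- grow_layers(seed_mask, candidate_mask, config$connectivity,
                   config$max_iterations)
  seg_mask(g$visited & !unclass(seed_mask), voxel_spacing(seed_mask))
}

#' Extract the periventricular-connected perivascular subnetwork
#'
#' Dilates the ventricle mask by the configured margin, then region-grows
#' it into the PVS segmentation, returning the portion of the perivascular
#' network continuous with perivascular voxels within the margin of the
#' ventricular surface.
#'
#' @param pvs_mask PVS \code{\link{seg_mask}}.
#' @param ventricle_mask ventricle \code{seg_mask}.
#' @param config a \code{\link{grow_config}}.
#' @return captured subnetwork \code{seg_mask} (subset of \code{pvs_mask}).
#' @export
extract_periventricular_network <- function(pvs_mask, ventricle_mask,
                                            config = grow_config()) {
  check_same_geometry(pvs_mask, ventricle_mask)
  seed <- dilate_mask(ventricle_mask, config$margin_voxels, config$connectivity)
  captured <- region_grow(seed, pvs_mask, config)
  # voxels of the PVS inside the dilated margin are part of the network too
  seg_mask((unclass(captured) | (unclass(seed) & unclass(pvs_mask))),
           voxel_spacing(pvs_mask))
}

#' Measure a perivascular segment length by centroid chaining
#'
#' Grows from a single seed voxel through the PVS mask; after each growth
#' iteration the centroid (mm) of the newly added voxels is recorded, and
#' the segment length is the sum of distances between consecutive
#' centroids, starting at the seed voxel center. Branching segments blend
#' centroids across branches — a documented bias of the simple procedure.
#'
#' @param pvs_mask PVS \code{\link{seg_mask}}.
#' @param seed_voxel integer length-3 voxel index (1-based) inside the
#'   mask, conventionally the surface end of the segment.
#' @param config a \code{\link{grow_config}}.
#' @return a \code{segment_path} list: \code{seed}, \code{centroids}
#'   (matrix, mm; first row is the seed center), \code{length_mm}.
#' @export
measure_segment_length <- function(pvs_mask, seed_voxel,
                                   config = grow_config()) {
  d <- dim(pvs_mask)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed_voxel must be a valid length-3 voxel index")
  if (!pvs_mask[seed_voxel[1L], seed_voxel[2L], seed_voxel[3L]])
    stop("seed voxel lies outside the segment mask")
  sp <- voxel_spacing(pvs_mask)
  seed <- array(FALSE, d)
  seed[seed_voxel[1L], seed_voxel[2L], seed_voxel[3L]] <- TRUE
  g <- grow_layers(seg_mask(seed, sp), pvs_mask, config$connectivity,
                   config$max_iterations)
  cents <- rbind((seed_voxel - 0.5) * sp)
  for (lin in g$layers) {
    ai <- arrayInd(lin, d)
    cents <- rbind(cents, colMeans(sweep(ai - 0.5, 2L, sp, "*")))
  }
  len <- if (nrow(cents) > 1L)
    sum(sqrt(rowSums((cents[-1L, , drop = FALSE] -
                        cents[-nrow(cents), , drop = FALSE])^2)))
  else 0
  structure(list(seed = seed_voxel, centroids = cents, length_mm = len),
            class = "segment_path")
}
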