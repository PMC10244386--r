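# Shared fixtures and independent oracles used across test files.

# Small brain-with-ventricle spec for fast end-to-end runs.
small_phantom_spec <- function(seed = 1L, tubes = NULL, noise_sd = 8,
                               bias = 0.05) {
  sp <- c(0.04, 0.04, 0.04)
  shape <- c(48L, 40L, 36L)
  ctr <- shape * sp / 2
  if (is.null(tubes))
    tubes <- list(tube_spec(rbind(ctr + c(-0.60, -0.10, 0.05),
                                  ctr + c(0.15, 0.12, 0.02)),
                            radius = 0.06, connects_ventricle = TRUE,
                            connects_surface = TRUE))
  phantom_spec(grid_shape = shape, spacing = sp,
               brain = list(center = ctr, semi_axes = c(0.85, 0.70, 0.60)),
               ventricle = list(list(type = "ellipsoid",
                                     center = ctr + c(0.25, 0.12, 0),
                                     semi_axes = c(0.18, 0.10, 0.10))),
               tubes = tubes, noise_sd = noise_sd, bias_amplitude = bias,
               parenchyma_level = 100, csf_level = 500, tube_level = 400,
               parenchyma_enhancement = 1.5, seed = seed)
}

# Drop mask class/attributes for bare-array comparisons against oracles.
strip_mask <- function(x) array(as.logical(x), dim(x))

# Brute-force anisotropic nearest-CSF-voxel search (all pairs).
brute_force_edt <- function(csf, spacing) {
  d <- dim(csf)
  idx <- which(csf)
  stopifnot(length(idx) > 0)
  ci <- arrayInd(idx, d)
  out <- array(NA_real_, d)
  all_i <- arrayInd(seq_len(prod(d)), d)
  for (v in seq_len(prod(d))) {
    dd <- sweep(ci, 2L, all_i[v, ], "-")
    dd <- sweep(dd, 2L, spacing, "*")
    out[v] <- sqrt(min(rowSums(dd^2)))
  }
  out
}

# Brute-force binary dilation: union of neighborhoods of set voxels.
brute_force_dilate <- function(mask, margin, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  m <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = m <= 1, "18" = m <= 2, "26" = m <= 3), ]
  cur <- mask
  for (rep in seq_len(margin)) {
    nxt <- cur
    set <- arrayInd(which(cur), d)
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(set, 2L, as.numeric(offs[r, ]), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nxt[nb[ok, , drop = FALSE]] <- TRUE
    }
    cur <- nxt
  }
  cur
}

# Queue-based BFS through candidate voxels from a seed set, capped at
# max_layers breadth levels beyond the seed; independent of the package's
# frontier/layer implementation.
bfs_capture <- function(seed, candidate, connectivity, max_layers) {
  d <- dim(seed)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1), ,
               drop = FALSE]
  dist <- array(Inf, d)
  dist[seed] <- 0
  queue <- arrayInd(which(seed), d)
  while (nrow(queue)) {
    nxt <- NULL
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(queue, 2L, offs[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lev <- dist[queue[ok, , drop = FALSE]] + 1
      for (q in seq_len(nrow(nb))) {
        if (candidate[nb[q, 1], nb[q, 2], nb[q, 3]] &&
            dist[nb[q, 1], nb[q, 2], nb[q, 3]] > lev[q] &&
            lev[q] <= max_layers) {
          dist[nb[q, 1], nb[q, 2], nb[q, 3]] <- lev[q]
          nxt <- rbind(nxt, nb[q, , drop = FALSE])
        }
      }
    }
    queue <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else nxt
  }
  is.finite(dist) & !seed
}

# Explicit finite-difference solution of dC/dt = kD d2C/dx2 on [0, L] with
# C(0) = 1, C(L) = 0, C(x, 0) = 0; returns alpha at the node positions.
fd_dispersion <- function(D, k, t_end, dx = 20, L = 4000) {
  kD <- k * D
  nx <- round(L / dx) + 1L
  dt <- 0.4 * dx^2 / (2 * kD)
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  a <- numeric(nx)
  a[1] <- 1
  r <- kD * dt / dx^2
  for (s in seq_len(nt)) {
    a[2:(nx - 1)] <- a[2:(nx - 1)] +
      r * (a[3:nx] - 2 * a[2:(nx - 1)] + a[1:(nx - 2)])
  }
  list(x = (seq_len(nx) - 1) * dx, alpha = a)
}

# Sorted-array percentile with linear interpolation (independent re-statement
# of the type-7 definition used for calibration).
sorted_percentile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# The naive-calibrated segmentation recovery experiment, memoized so the
# module test and the acceptance suite share one run.
recovery_cache <- new.env(parent = emptyenv())
run_recovery_experiment <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  spec <- recovery_phantom_spec(seed)
  ph <- generate_phantom(spec)
  tcfg <- tubeness_config()
  vol <- remap_intensity(ph$volume, ph$truth$brain_mask, tcfg$reference_peak)
  naive <- lapply(1:2, function(i) {
    s <- spec; s$seed <- spec$seed + 1000L * i
    remap_intensity(generate_naive(s), ph$truth$brain_mask, tcfg$reference_peak)
  })
  tub <- compute_tubeness(vol, tcfg)
  ntub <- lapply(naive, compute_tubeness, config = tcfg)
  regions <- brain_regions(ph$truth$brain_mask, tcfg$surface_shell_thickness)
  thresholds <- calibrate_threshold(ntub, regions, tcfg$interior_quantile)
  pvs <- segment_pvs(tub, thresholds, regions, ph$truth$brain_mask)
  sp <- voxel_spacing(pvs)
  seg_interior <- seg_mask(unclass(pvs) & unclass(regions$interior), sp)
  truth_interior <- seg_mask(unclass(ph$truth$pvs_mask) & unclass(regions$interior), sp)
  res <- list(spec = spec, phantom = ph, thresholds = thresholds,
              pvs = pvs, regions = regions,
              dice_interior = dice_coefficient(seg_interior, truth_interior))
  recovery_cache[[key]] <- res
  res
}
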