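#' Dice similarity coefficient of two masks
#' @param a,b \code{\link{seg_mask}}s sharing geometry.
#' @return \code{2|a & b| / (|a| + |b|)} (1 if both are empty).
#' @export
dice_coefficient <- function(a, b) {
  check_same_geometry(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Run the full perivascular analysis pipeline on a phantom
#'
#' Ties the stages together: simulate (contrast phantom + naive controls)
#' -> project -> intensity peak alignment -> tubeness -> naive-calibrated
#' segmentation -> periventricular network extraction and segment lengths
#' -> clearance distance maps and time scales (with and without PVS as
#' CSF) -> dispersion traversal table. Writes NIfTI masks, CSV statistics
#' and a JSON manifest recording the configuration hash, thresholds and
#' all derived statistics; reruns with the same config are deterministic.
#'
#' @param config configuration list (or path to a YAML file with the same
#'   structure) with optional entries: \code{seed} (default 1),
#'   \code{n_naive} (default 2), \code{phantom_spec} (default
#'   \code{\link{default_phantom_spec}}), \code{tubeness} (arguments to
#'   \code{\link{tubeness_config}}), \code{grow} (arguments to
#'   \code{\link{grow_config}}), \code{clearance} (list with \code{D_star},
#'   um^2/s, default 62.3, and optional \code{u}, um/s), \code{dispersion}
#'   (arguments to \code{\link{traversal_table}}), \code{projection}
#'   (list with \code{axis}, \code{thickness}), and \code{output_dir}
#'   (default: no files are written).
#' @return (invisibly) the manifest list; written to
#'   \code{manifest.json} when \code{output_dir} is set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  n_naive <- as.integer(config$n_naive %||% 2L)
  if (n_naive < 1L)
    stop("stage 'calibrate': at least one naive control volume is required")
  tcfg <- do.call(tubeness_config, config$tubeness %||% list())
  gcfg <- do.call(grow_config, config$grow %||% list())
  D_star <- (config$clearance %||% list())$D_star %||% 62.3
  outdir <- config$output_dir

  # --- simulate -------------------------------------------------------------
  spec <- config$phantom_spec %||% default_phantom_spec(seed = seed)
  ph <- generate_phantom(spec)
  naive_specs <- lapply(seq_len(n_naive), function(i) {
    s <- spec; s$seed <- seed + 1000L * i; s
  })
  naives <- lapply(naive_specs, generate_naive)
  truth <- ph$truth

  # --- project --------------------------------------------------------------
  pcfg <- config$projection %||% list(axis = 1L, thickness = 30L)
  n_ax <- dim(ph$volume)[resolve_axis(pcfg$axis)]
  mid <- max(1L, (n_ax - pcfg$thickness) %/% 2L + 1L)
  pmip <- partial_mip(ph$volume, pcfg$axis, mid, pcfg$thickness)

  # --- align + tubeness + calibrate + segment -------------------------------
  vol <- remap_intensity(ph$volume, truth$brain_mask, tcfg$reference_peak)
  scale_factor <- attr(vol, "scale_factor")
  naives <- lapply(naives, remap_intensity, brain_mask = truth$brain_mask,
                   reference_peak = tcfg$reference_peak)
  tub <- compute_tubeness(vol, tcfg)
  naive_tub <- lapply(naives, compute_tubeness, config = tcfg)
  regions <- brain_regions(truth$brain_mask, tcfg$surface_shell_thickness)
  thresholds <- calibrate_threshold(naive_tub, regions, tcfg$interior_quantile)
  pvs <- segment_pvs(tub, thresholds, regions, truth$brain_mask,
                     truth$ventricle_mask)

  # --- network --------------------------------------------------------------
  network <- extract_periventricular_network(pvs, truth$ventricle_mask, gcfg)
  capture_flags <- vapply(seq_along(truth$tube_lengths), function(i) {
    vox <- truth$tube_labels == i
    any(network & vox)
  }, logical(1))
  seg_lengths <- vapply(seq_along(truth$tube_lengths), function(i) {
    vox <- which(truth$tube_labels == i & unclass(pvs))
    if (!length(vox)) return(NA_real_)
    measure_segment_length(pvs, arrayInd(vox[1L], dim(pvs))[1L, ],
                           gcfg)$length_mm
  }, numeric(1))

  # --- clearance ------------------------------------------------------------
  d_without <- distance_to_csf(truth$ventricle_mask, truth$brain_mask)
  d_with <- distance_to_csf(truth$ventricle_mask, truth$brain_mask, pvs)
  st_without <- mcd_stats(d_without)
  st_with <- mcd_stats(d_with, attr(d_without, "parenchyma_mask"))
  clearance <- list(
    mcd_mean_mm = c(without_pvs = st_without$mean, with_pvs = st_with$mean),
    mcd_sd_mm = c(without_pvs = st_without$sd, with_pvs = st_with$sd),
    tau_d_s = c(without_pvs = diffusive_time(st_without$mean, D_star),
                with_pvs = diffusive_time(st_with$mean, D_star)),
    fold_reduction = (st_without$mean / st_with$mean)^2,
    D_star = D_star)

  # --- dispersion -----------------------------------------------------------
  disp <- do.call(traversal_table, config$dispersion %||% list())

  manifest <- list(
    package_version = as.character(utils::packageVersion("pvsnet")),
    seed = seed,
    config_hash = hash_config(config),
    intensity_scale_factor = scale_factor,
    thresholds = as.list(thresholds),
    segmentation = list(
      n_pvs_voxels = sum(pvs),
      dice_vs_truth = dice_coefficient(pvs, truth$pvs_mask),
      dice_vs_truth_interior = dice_coefficient(
        seg_mask(unclass(pvs) & unclass(regions$interior), spec$spacing),
        seg_mask(unclass(truth$pvs_mask) & unclass(regions$interior),
                 spec$spacing)),
      percent_volume_brain = percent_volume(pvs, truth$brain_mask)),
    network = list(captured_tube = capture_flags,
                   truth_connects_ventricle = truth$connects_ventricle,
                   segment_length_mm = seg_lengths,
                   truth_length_mm = truth$tube_lengths),
    clearance = clearance)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_volume(pvs, file.path(outdir, "pvs.nii.gz"))
    write_volume(network, file.path(outdir, "periventricular_network.nii.gz"))
    write_volume(d_with, file.path(outdir, "mcd_with_pvs.nii.gz"))
    write_volume(d_without, file.path(outdir, "mcd_without_pvs.nii.gz"))
    utils::write.csv(disp, file.path(outdir, "dispersion_times.csv"),
                     row.names = FALSE)
    write_mip_stack(pmip, outdir, "pmip")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest$dispersion <- disp
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hash_config <- function(config) {
  config$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}
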