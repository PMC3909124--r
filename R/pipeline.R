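# End-to-end orchestration: volume -> denoising -> lung/airway segmentation
# -> ROI -> vessel enhancement -> centerline candidates -> linking ->
# segments -> morphometric readouts, plus the cohort-level report.

#' Pipeline configuration
#'
#' All tunable parameters of the per-patient pipeline with their defaults.
#' The resolved configuration is serialised next to every output for
#' provenance.
#'
#' @param working_spacing_mm isotropic resampling target (default 0.6, the
#'   acquisition slice thickness).
#' @param tv_weight,tv_iters denoising strength and iterations.
#' @param closing_radius_mm lung mask closing ball.
#' @param airway_margin_mm bronchial wall margin removed from the ROI.
#' @param sigmas VEF scale set in mm.
#' @param nms_floor_frac response floor as a fraction of the 99.9th
#'   percentile of the in-ROI response.
#' @param adjacency_factor candidate linking radius in working voxels.
#' @param prune_mm spur-pruning length threshold.
#' @param smooth_window polyline smoothing window (odd, 1 = off).
#' @param min_seg_points minimum points per admissible segment.
#' @param delta_max largest box-counting cube size (pixels).
#' @param r2_good linear-range fit threshold for the fractal dimension.
#' @param seed seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(working_spacing_mm = 0.6, tv_weight = 20,
                            tv_iters = 40, closing_radius_mm = 5,
                            airway_margin_mm = 2,
                            sigmas = c(0.6, 1, 1.5, 2.25, 3.4, 5),
                            nms_floor_frac = 0.1, adjacency_factor = 2,
                            prune_mm = 2, smooth_window = 3,
                            min_seg_points = 3, delta_max = 100,
                            r2_good = 0.99, seed = 1) {
  cfg <- list(working_spacing_mm = working_spacing_mm, tv_weight = tv_weight,
              tv_iters = tv_iters, closing_radius_mm = closing_radius_mm,
              airway_margin_mm = airway_margin_mm, sigmas = sigmas,
              nms_floor_frac = nms_floor_frac,
              adjacency_factor = adjacency_factor, prune_mm = prune_mm,
              smooth_window = smooth_window, min_seg_points = min_seg_points,
              delta_max = delta_max, r2_good = r2_good, seed = seed)
  stopifnot(working_spacing_mm > 0, tv_weight > 0, tv_iters >= 1,
            closing_radius_mm >= 0, airway_margin_mm >= 0,
            all(diff(sigmas) > 0), nms_floor_frac >= 0,
            adjacency_factor > 0, prune_mm >= 0, delta_max > 1)
  class(cfg) <- "pipeline_config"
  cfg
}

write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ", ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

stage_log <- function(verbose, stage, t0, extra = "") {
  if (verbose)
    message(sprintf("[vastrac] %-18s %6.1fs %s", stage,
                    as.numeric(Sys.time() - t0, units = "secs"), extra))
}

#' Run the full pipeline on one patient volume
#'
#' Executes the stages in order: read, isotropic resampling, TV denoising,
#' lung segmentation, airway segmentation (skipped with a warning when no
#' airway is found, as in airway-free phantoms), ROI construction, vessel
#' enhancement, non-maxima suppression, centerline linking with spur
#' pruning, segment decomposition, and the morphometric readouts (mean
#' distance metric in mm space; fractal dimension of the candidate point
#' set in working-voxel units).
#'
#' @param volume a [volume3d()] or a file path readable by [read_volume()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: writes `metrics.json`,
#'   `config.txt`, masks as NIfTI and centerlines as VTK polylines.
#' @param verbose log per-stage timings and counts to stderr.
#' @return A list: `metrics` (`mean_dm`, `fd`, `fd_r2`, `n_segments`,
#'   `n_candidates`), `segments`, `graph`, `candidates`, `lung`, `roi`,
#'   `airway`, `config`.
#' @export
run_patient <- function(volume, config = pipeline_config(), out_dir = NULL,
                        verbose = FALSE) {
  t0 <- Sys.time()
  v <- if (inherits(volume, "volume3d")) volume else read_volume(volume)
  if (!isTRUE(all.equal(v$spacing,
                        rep(config$working_spacing_mm, 3), tolerance = 1e-6)))
    v <- resample_isotropic(v, config$working_spacing_mm)
  stage_log(verbose, "resample", t0, paste(dim(v$data), collapse = "x"))
  den <- tv_denoise(v, config$tv_weight, config$tv_iters)
  stage_log(verbose, "tv_denoise", t0)
  lung <- segment_lung(den, config$closing_radius_mm)
  stage_log(verbose, "segment_lung", t0, sprintf("%d voxels", sum(lung$data)))
  aw <- tryCatch(segment_airways(den, lung), error = function(e) {
    warning("airway segmentation skipped: ", conditionMessage(e))
    NULL
  })
  airway <- if (is.null(aw))
    mask3d(array(0, dim(v$data)), v$spacing, v$origin) else aw$airway_mask
  stage_log(verbose, "segment_airways", t0,
            if (is.null(aw)) "none" else sprintf("%d voxels", sum(airway$data)))
  roi <- build_roi(lung, airway, config$airway_margin_mm)
  stopifnot(sum(roi$data * airway$data) == 0)
  vv <- vef_response(den, roi, scale_space_params(sigmas = config$sigmas))
  stage_log(verbose, "vef_response", t0)
  vals <- vv$response$data[vv$roi_idx]
  thr <- if (any(vals > 0))
    config$nms_floor_frac * as.numeric(quantile(vals[vals > 0], 0.999)) else 0
  cands <- non_maxima_suppression(vv, thr)
  stage_log(verbose, "nms", t0, sprintf("%d candidates", nrow(cands)))
  g <- link_candidates(cands, vv,
                       config$adjacency_factor * config$working_spacing_mm)
  g <- prune_spurs(g, config$prune_mm)
  segs <- decompose_segments(g)
  segs <- smooth_segments(segs, config$smooth_window)
  if (nrow(cands) > 0 && length(segs) > 0)
    segs <- debias_segments(segs, cands$scale)
  stage_log(verbose, "centerlines", t0, sprintf("%d segments", length(segs)))
  nseg <- count_segments(segs, config$min_seg_points,
                         config$working_spacing_mm)
  mean_dm <- if (nseg > 0)
    mean_distance_metric(segs, config$min_seg_points,
                         config$working_spacing_mm) else NA_real_
  fd_fit <- NULL
  if (nrow(cands) >= 2) {
    pts_vox <- cbind((cands$x_mm - v$origin[1]) / v$spacing[1],
                     (cands$y_mm - v$origin[2]) / v$spacing[2],
                     (cands$z_mm - v$origin[3]) / v$spacing[3])
    fd_fit <- tryCatch(fractal_dimension(pts_vox, 1, config$delta_max,
                                         config$r2_good),
                       error = function(e) NULL)
  }
  metrics <- list(mean_dm = mean_dm,
                  fd = if (is.null(fd_fit)) NA_real_ else fd_fit$fd,
                  fd_r2 = if (is.null(fd_fit)) NA_real_ else fd_fit$r2,
                  n_segments = nseg, n_candidates = nrow(cands))
  stage_log(verbose, "metrics", t0,
            sprintf("dm=%.4f fd=%.3f nseg=%d", metrics$mean_dm,
                    metrics$fd, metrics$n_segments))
  res <- list(metrics = metrics, segments = segs, graph = g,
              candidates = cands, lung = lung, roi = roi, airway = airway,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.txt"))
    write_volume(lung, file.path(out_dir, "lung_mask.nii.gz"))
    write_volume(roi, file.path(out_dir, "roi_mask.nii.gz"))
    write_volume(airway, file.path(out_dir, "airway_mask.nii.gz"))
    if (length(segs) > 0)
      write_segments_vtk(segs, file.path(out_dir, "centerlines.vtk"))
    write.csv(cands, file.path(out_dir, "candidates.csv"), row.names = FALSE)
  }
  res
}

#' Run the cohort statistics stage
#'
#' Joins per-patient morphometry with a hemodynamics table by `patient_id`
#' and produces the cohort report.
#'
#' @param hemodynamics data frame or CSV path with one row per patient
#'   (`patient_id`, `mPAP`, `PVR`, ... , `who_class`); a `ph_label` column
#'   is derived as `mPAP >= 25` when absent.
#' @param metrics data frame or CSV path with `patient_id`, `mean_dm`, and
#'   optionally `fd`, `n_segments`; may be omitted when `hemodynamics`
#'   already carries the morphometry columns.
#' @param var_equal,out_dir see [cohort_report()] / [write_cohort_report()].
#' @return A `cohort_report`.
#' @export
run_cohort <- function(hemodynamics, metrics = NULL, var_equal = TRUE,
                       out_dir = NULL) {
  hemo <- if (is.character(hemodynamics)) read.csv(hemodynamics) else
    as.data.frame(hemodynamics)
  if (nrow(hemo) < 6) stop("need at least 6 patients")
  if (!is.null(metrics)) {
    met <- if (is.character(metrics)) read.csv(metrics) else
      as.data.frame(metrics)
    if (!("patient_id" %in% names(hemo)) || !("patient_id" %in% names(met)))
      stop("both tables need a `patient_id` column")
    only_h <- setdiff(hemo$patient_id, met$patient_id)
    only_m <- setdiff(met$patient_id, hemo$patient_id)
    if (length(only_h) > 0 || length(only_m) > 0)
      stop("mismatched patient IDs: ",
           paste(unique(c(only_h, only_m)), collapse = ", "))
    hemo <- merge(hemo, met, by = "patient_id")
  }
  if (!("ph_label" %in% names(hemo))) {
    if (!("mPAP" %in% names(hemo)))
      stop("need `ph_label` or `mPAP` to define the PH groups")
    hemo$ph_label <- hemo$mPAP >= 25
  }
  rep <- cohort_report(hemo, var_equal = var_equal)
  if (!is.null(out_dir)) write_cohort_report(rep, out_dir)
  rep
}
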