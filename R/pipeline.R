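## Pipeline orchestration: simulate -> preprocess -> rows -> mosaic ->
## stats -> eval as resumable stages driven by one YAML-serializable
## configuration, with plain-file outputs and a JSON run manifest.

#' Default pipeline configuration
#'
#' All stage parameters in one nested list; round-trips losslessly
#' through YAML.  The capture defaults (85% overlap, cell = 80% of the
#' cropped footprint) guarantee that every grid cell is fully covered by
#' its nearest image, the precondition for exact head conservation
#' through the mosaic.
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    field = list(n_rows = 6, row_spacing_m = 0.75, row_length_m = 8,
                 heads_per_m = 6, orientation_deg = 0,
                 cross_jitter_sd_m = 0.02, head_diameter_cm = 10,
                 origin_lat = -27.45, origin_lon = 151.53),
    capture = list(gsd_cm_px = 0.5, image_w_px = 1600, image_h_px = 1600,
                   overlap_fraction = 0.6, margin_m = 2),
    noise = list(enabled = FALSE, fp_rate_per_m2 = 0.05, fn_prob = 0.1,
                 box_jitter_px_sd = 2),
    preprocess = list(edge_fraction = 0.1, target_gsd_cm_px = 0.5),
    rows = list(n = 2, k = 500, t_px = NULL, d = 5,
                direction_tol_deg = 10),
    mosaic = list(cell_fraction = 0.5, field_margin_m = 0.5),
    stats = list(gap_threshold_cm = 50, row_window_cm = 100,
                 row_sigma_cm = 25, map_window_px = 100,
                 map_scale_cm_px = 1, map_kernel_size = 101),
    eval = list(iou_thresh = 0.5)
  )
}

#' Validate a pipeline configuration
#'
#' Schema check with named messages; unknown keys produce warnings, not
#' errors (forward compatibility).
#'
#' @param config configuration list, or path to a YAML file.
#' @return `list(ok, errors, warnings)`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errors <- character(); warnings <- character()
  ref <- default_config()
  known <- names(ref)
  for (nm in setdiff(names(config), known)) {
    warnings <- c(warnings, sprintf("unknown section '%s' ignored", nm))
  }
  extra_keys <- list(mosaic = "cell_m", field = "gaps")
  for (sec in intersect(names(config), known)) {
    if (!is.list(config[[sec]])) next
    ok_keys <- c(names(ref[[sec]]), extra_keys[[sec]])
    for (nm in setdiff(names(config[[sec]]), ok_keys)) {
      warnings <- c(warnings,
                    sprintf("unknown key '%s.%s' ignored", sec, nm))
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  f <- config$field
  if (!is.null(f)) {
    chk(is.null(f$row_spacing_m) || f$row_spacing_m > 0,
        "field.row_spacing_m must be > 0")
    chk(is.null(f$row_length_m) || f$row_length_m > 0,
        "field.row_length_m must be > 0")
    chk(is.null(f$heads_per_m) || all(f$heads_per_m >= 0),
        "field.heads_per_m must be >= 0")
  }
  cp <- config$capture
  if (!is.null(cp)) {
    chk(is.null(cp$gsd_cm_px) || cp$gsd_cm_px > 0,
        "capture.gsd_cm_px must be > 0")
    chk(is.null(cp$overlap_fraction) ||
          (cp$overlap_fraction >= 0 && cp$overlap_fraction < 1),
        "capture.overlap_fraction must be in [0, 1)")
  }
  pp <- config$preprocess
  if (!is.null(pp)) {
    chk(is.null(pp$edge_fraction) ||
          (pp$edge_fraction >= 0 && pp$edge_fraction < 0.5),
        "preprocess.edge_fraction must be in [0, 0.5)")
    chk(is.null(pp$target_gsd_cm_px) || pp$target_gsd_cm_px > 0,
        "preprocess.target_gsd_cm_px must be > 0")
  }
  rw <- config$rows
  if (!is.null(rw)) {
    chk(is.null(rw$n) || rw$n >= 2, "rows.n must be >= 2")
    chk(is.null(rw$t_px) || rw$t_px > 0, "rows.t_px must be > 0")
    chk(is.null(rw$d) || is.null(rw$n) || rw$d >= rw$n,
        "rows.d must be >= rows.n")
  }
  ns <- config$noise
  if (!is.null(ns)) {
    chk(is.null(ns$fn_prob) || (ns$fn_prob >= 0 && ns$fn_prob <= 1),
        "noise.fn_prob must be in [0, 1]")
    chk(is.null(ns$fp_rate_per_m2) || ns$fp_rate_per_m2 >= 0,
        "noise.fp_rate_per_m2 must be >= 0")
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

## fill missing keys of config from the defaults, recursively
merge_config <- function(config, ref = default_config()) {
  for (nm in names(ref)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- ref[[nm]]
    } else if (is.list(ref[[nm]])) {
      for (k in names(ref[[nm]])) {
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- ref[[nm]][[k]]
      }
    }
  }
  config
}

log_info <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

## rebuild the per-image rows structure (as produced by
## detect_rows_images) from rows.json + the preprocessed detections
load_per_image <- function(rows_path, dets, meta) {
  rj <- jsonlite::read_json(rows_path, simplifyVector = FALSE)
  out <- list()
  for (id in names(rj)) {
    e <- rj[[id]]
    rec <- meta[meta$image_id == id, , drop = FALSE]
    d <- dets[dets$image_id == id, , drop = FALSE]
    theta <- e$theta_deg
    if (is.null(theta)) theta <- NA_real_
    rot <- if (!is.na(theta)) rotate_to_horizontal(d, rec, theta) else
      list(detections = d, rotation = NULL)
    rows <- lapply(e$rows, function(m) {
      structure(list(a = m$a, b = m$b,
                     inlier_ids = unlist(m$inlier_ids),
                     x_span = unlist(m$x_span),
                     mean_residual = NA_real_,
                     n_inliers = m$n_inliers),
                class = "row_model")
    })
    out[[id]] <- list(theta_deg = theta, rotation = rot$rotation,
                      detections = rot$detections,
                      rows = structure(rows, class = "row_set"))
  }
  out
}

#' Run the deployment pipeline
#'
#' Executes the requested stages in order -- `simulate` (synthetic field,
#' captures, optional detector noise), `preprocess` (center crop + GSD
#' rescale), `rows` (per-image dominant direction, horizontal correction,
#' iterative RANSAC), `mosaic` (grid, nearest-image assignment,
#' field-frame detections), `stats` (per-image statistics, gaps, field
#' density map), `eval` (detector metrics against the simulated truth) --
#' writing plain CSV/JSON outputs per stage plus a run manifest.  Any
#' stage can resume from the files written by an earlier invocation with
#' the same `out_dir`.
#'
#' @param config configuration list (see [default_config()]) or a YAML
#'   path; missing keys fall back to the defaults.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run, in pipeline order.
#' @param quiet suppress per-stage log messages.
#' @return the run manifest list, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "preprocess", "rows",
                                    "mosaic", "stats", "eval"),
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- validate_config(config)
  if (!v$ok) {
    stopf("invalid configuration:\n%s", paste(v$errors, collapse = "\n"),
          class = "paniclepipe_config_error")
  }
  config <- merge_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("paniclepipe")),
                   r_version = R.version.string)
  paths <- list(
    truth = file.path(out_dir, "truth.json"),
    meta = file.path(out_dir, "meta.csv"),
    gt = file.path(out_dir, "detections_truth.csv"),
    det = file.path(out_dir, "detections.csv"),
    pmeta = file.path(out_dir, "meta_preprocessed.csv"),
    pdet = file.path(out_dir, "detections_preprocessed.csv"),
    rows = file.path(out_dir, "rows.json"),
    field = file.path(out_dir, "field_detections.csv"),
    grid = file.path(out_dir, "grid.json"),
    stats = file.path(out_dir, "image_stats.csv"),
    gaps = file.path(out_dir, "gaps.csv"),
    map_csv = file.path(out_dir, "density_map.csv"),
    map_meta = file.path(out_dir, "density_map.json"),
    metrics = file.path(out_dir, "metrics.json"),
    manifest = file.path(out_dir, "manifest.json"))

  state <- list()

  if ("simulate" %in% stages) {
    fc <- config$field
    truth <- generate_field(field_config(
      n_rows = fc$n_rows, row_spacing_m = fc$row_spacing_m,
      row_length_m = fc$row_length_m, heads_per_m = fc$heads_per_m,
      orientation_deg = fc$orientation_deg,
      cross_jitter_sd_m = fc$cross_jitter_sd_m,
      head_diameter_cm = fc$head_diameter_cm,
      gaps = if (!is.null(fc$gaps)) as.data.frame(fc$gaps) else NULL,
      origin_lat = fc$origin_lat, origin_lon = fc$origin_lon,
      seed = config$seed))
    cc <- config$capture
    cap <- capture_config(gsd_cm_px = cc$gsd_cm_px,
                          image_w_px = cc$image_w_px,
                          image_h_px = cc$image_h_px,
                          overlap_fraction = cc$overlap_fraction,
                          margin_m = cc$margin_m)
    capd <- capture_images(truth, cap)
    dets <- capd$detections
    if (isTRUE(config$noise$enabled)) {
      noise <- detector_noise(
        fp_rate_per_m2 = config$noise$fp_rate_per_m2,
        fn_prob = config$noise$fn_prob,
        box_jitter_px_sd = config$noise$box_jitter_px_sd,
        seed = config$seed + 1L)
      dets <- corrupt_detections(capd$detections, noise, capd$meta)
    }
    write_truth_manifest(truth, paths$truth)
    write_image_meta(capd$meta, paths$meta)
    write_detections(capd$detections, paths$gt)
    write_detections(dets, paths$det)
    state$truth <- truth; state$meta <- capd$meta
    state$gt <- capd$detections; state$dets <- dets
    manifest$stages$simulate <- list(
      images = nrow(capd$meta), heads = nrow(truth$heads),
      gt_boxes = nrow(capd$detections), detections = nrow(dets))
    log_info(quiet, "simulate: %d heads, %d images, %d detections",
             nrow(truth$heads), nrow(capd$meta), nrow(dets))
  }

  if ("preprocess" %in% stages) {
    meta <- state$meta %||% read_image_meta(paths$meta)
    dets <- state$dets %||% read_detections(paths$det)
    pp <- config$preprocess
    pm <- list(); pd <- list()
    for (i in seq_len(nrow(meta))) {
      rec <- meta[i, , drop = FALSE]
      d <- dets[dets$image_id == rec$image_id, , drop = FALSE]
      cr <- center_crop(rec, d, pp$edge_fraction)
      rs <- rescale_to_gsd(cr$record, cr$detections, pp$target_gsd_cm_px)
      pm[[i]] <- rs$record; pd[[i]] <- rs$detections
    }
    meta2 <- do.call(rbind, pm)
    dets2 <- do.call(rbind, pd)
    rownames(meta2) <- rownames(dets2) <- NULL
    write_image_meta(meta2, paths$pmeta)
    write_detections(dets2, paths$pdet)
    state$pmeta <- meta2; state$pdets <- dets2
    manifest$stages$preprocess <- list(images = nrow(meta2),
                                       detections = nrow(dets2))
    log_info(quiet, "preprocess: kept %d detections", nrow(dets2))
  }

  if ("rows" %in% stages) {
    meta <- state$pmeta %||% read_image_meta(paths$pmeta)
    dets <- state$pdets %||% read_detections(paths$pdet)
    rw <- config$rows
    spacing_px <- config$field$row_spacing_m * 100 /
      config$preprocess$target_gsd_cm_px
    params <- ransac_params(n = rw$n, k = rw$k, t = rw$t_px, d = rw$d,
                            row_spacing_px = spacing_px,
                            seed = config$seed + 2L)
    per_image <- detect_rows_images(dets, meta, params,
                                    tol_deg = rw$direction_tol_deg)
    rows_json <- lapply(per_image, function(e) {
      list(theta_deg = e$theta_deg,
           rotation = e$rotation,
           rows = lapply(e$rows, function(m) {
             list(a = m$a, b = m$b, x_span = m$x_span,
                  n_inliers = m$n_inliers, inlier_ids = m$inlier_ids)
           }))
    })
    jsonlite::write_json(rows_json, paths$rows, auto_unbox = TRUE,
                         digits = NA, null = "null")
    state$per_image <- per_image
    n_rows_total <- sum(vapply(per_image,
                               function(e) length(e$rows), 0L))
    manifest$stages$rows <- list(images = length(per_image),
                                 rows = n_rows_total)
    log_info(quiet, "rows: %d row models across %d images", n_rows_total,
             length(per_image))
  }

  if ("mosaic" %in% stages) {
    meta <- state$pmeta %||% read_image_meta(paths$pmeta)
    per_image <- state$per_image %||%
      load_per_image(paths$rows,
                     state$pdets %||% read_detections(paths$pdet), meta)
    state$per_image <- per_image
    cell_m <- config$mosaic$cell_m %||%
      default_cell_size(meta, config$mosaic$cell_fraction)
    truth <- state$truth
    extent_local <- if (!is.null(truth)) {
      field_extent(truth, margin_m = config$mosaic$field_margin_m)
    } else if (file.exists(paths$truth)) {
      tj <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
      th <- deg2rad(tj$config$orientation_deg)
      along <- c(0, tj$config$row_length_m)
      cross <- range(tj$rows$cross_m)
      corners <- expand.grid(a = along, c = cross)
      xx <- cos(th) * corners$a - sin(th) * corners$c
      yy <- sin(th) * corners$a + cos(th) * corners$c
      m0 <- config$mosaic$field_margin_m
      c(min(xx) - m0, max(xx) + m0, min(yy) - m0, max(yy) + m0)
    } else NULL
    qm <- quasi_mosaic(per_image, meta,
                       ref_lat = config$field$origin_lat,
                       ref_lon = config$field$origin_lon,
                       cell_m = cell_m, extent_local = extent_local)
    utils::write.csv(qm$field_detections, paths$field, row.names = FALSE)
    jsonlite::write_json(
      list(extent_m = qm$grid$extent, m_x = qm$grid$m_x,
           m_y = qm$grid$m_y, n_cols = qm$grid$n_cols,
           n_rows = qm$grid$n_rows, rotation_deg = qm$rotation_deg,
           assignment = qm$grid$assignment),
      paths$grid, auto_unbox = TRUE, digits = NA, null = "null")
    state$qm <- qm
    manifest$stages$mosaic <- list(
      cells = qm$grid$n_cols * qm$grid$n_rows,
      assigned = sum(!is.na(qm$grid$assignment)),
      field_detections = nrow(qm$field_detections))
    log_info(quiet, "mosaic: %d/%d cells assigned, %d field detections",
             sum(!is.na(qm$grid$assignment)),
             qm$grid$n_cols * qm$grid$n_rows, nrow(qm$field_detections))
  }

  if ("stats" %in% stages) {
    meta <- state$pmeta %||% read_image_meta(paths$pmeta)
    per_image <- state$per_image %||%
      load_per_image(paths$rows,
                     state$pdets %||% read_detections(paths$pdet), meta)
    st <- config$stats
    stats_rows <- list(); gaps_rows <- list()
    for (id in names(per_image)) {
      rec <- meta[meta$image_id == id, , drop = FALSE]
      isx <- image_stats(per_image[[id]]$detections, rec,
                         per_image[[id]]$rows, st$gap_threshold_cm)
      if (nrow(isx$per_row)) {
        stats_rows[[id]] <- cbind(image_id = id, isx$per_row,
                                  c_i = isx$c_i, d_i = isx$d_i)
      }
      if (nrow(isx$gaps)) gaps_rows[[id]] <- cbind(image_id = id, isx$gaps)
    }
    stats_df <- do.call(rbind, stats_rows) %||%
      data.frame(image_id = character())
    gaps_df <- do.call(rbind, gaps_rows) %||%
      data.frame(image_id = character())
    rownames(stats_df) <- rownames(gaps_df) <- NULL
    utils::write.csv(stats_df, paths$stats, row.names = FALSE)
    utils::write.csv(gaps_df, paths$gaps, row.names = FALSE)
    fd <- if (!is.null(state$qm)) state$qm$field_detections else
      utils::read.csv(paths$field, stringsAsFactors = FALSE)
    map <- field_density_map(fd, window_px = st$map_window_px,
                             scale_cm_px = st$map_scale_cm_px,
                             kernel_size = st$map_kernel_size)
    write_density_map(map, paths$map_csv, paths$map_meta)
    state$map <- map
    manifest$stages$stats <- list(
      images = length(stats_rows), gaps = nrow(gaps_df),
      map_px = ncol(map$density) * nrow(map$density),
      density_range = range(map$density))
    log_info(quiet, "stats: %d gap records, density range %.2f-%.2f heads/m^2",
             nrow(gaps_df), min(map$density), max(map$density))
  }

  if ("eval" %in% stages) {
    gt <- state$gt %||% read_detections(paths$gt)
    dets <- state$dets %||% read_detections(paths$det)
    ev <- evaluate_detections(dets, gt, config$eval$iou_thresh)
    jsonlite::write_json(list(ap = ev$ap, mae = ev$mae, rmse = ev$rmse,
                              iou_thresh = config$eval$iou_thresh,
                              interpolation = ev$interpolation,
                              n_detections = nrow(dets), n_gt = nrow(gt)),
                         paths$metrics, auto_unbox = TRUE, digits = NA)
    manifest$stages$eval <- list(ap = ev$ap, mae = ev$mae, rmse = ev$rmse)
    log_info(quiet, "eval: AP %.3f, MAE %.2f, RMSE %.2f", ev$ap, ev$mae,
             ev$rmse)
  }

  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
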