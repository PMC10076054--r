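## Quasi-mosaic construction: a GPS-anchored grid of cells over the field,
## each cell filled from the single nearest covering image, so that the
## per-image detections can be composed into one field-frame detection set
## (and optionally one raster composite) with overlaps removed purely by
## cell-exclusive cropping -- no feature matching, no box merging.

#' Build a field grid
#'
#' Lattice of `ceiling(width / m_x) x ceiling(height / m_y)` cells
#' covering a local-frame extent, with cell centers at half-cell offsets.
#' A cell larger than the extent degenerates to a valid single-cell grid
#' (with a warning).
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres (mosaic
#'   frame).
#' @param m_x,m_y cell sizes in metres; must be positive and (for
#'   assignment to succeed) smaller than the image ground coverage.
#' @return a `field_grid` list with `centers_x`, `centers_y`, and an
#'   `assignment` character matrix (`n_rows x n_cols`, `NA` = unassigned;
#'   row index j follows `centers_y`, column index i follows `centers_x`).
#' @export
build_grid <- function(extent, m_x, m_y = m_x) {
  if (!is_pos(m_x) || !is_pos(m_y)) stopf("cell sizes must be positive")
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (w <= 0 || h <= 0) stopf("degenerate extent")
  if (m_x > w || m_y > h) {
    warning("grid cell larger than the extent; using a single cell")
  }
  n_cols <- max(1L, ceiling(w / m_x))
  n_rows <- max(1L, ceiling(h / m_y))
  structure(list(extent = extent, m_x = m_x, m_y = m_y,
                 n_cols = n_cols, n_rows = n_rows,
                 centers_x = extent[1] + (seq_len(n_cols) - 0.5) * m_x,
                 centers_y = extent[3] + (seq_len(n_rows) - 0.5) * m_y,
                 assignment = matrix(NA_character_, n_rows, n_cols)),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field grid: %d x %d cells of %.2f x %.2f m, %d assigned\n",
              x$n_cols, x$n_rows, x$m_x, x$m_y, sum(!is.na(x$assignment))))
  invisible(x)
}

#' Camera positions in the mosaic frame
#'
#' Projects camera GPS to local metres about a reference point and
#' optionally rotates the frame so planting rows run horizontal in the
#' mosaic (`rotation_deg` is the image-frame dominant direction; the
#' east/north frame is rotated consistently with the per-image horizontal
#' correction).
#'
#' @param meta image metadata with GPS.
#' @param ref_lat,ref_lon reference point, degrees.
#' @param rotation_deg global mosaic rotation, degrees (default 0).
#' @return `data.frame(image_id, e, n, half_w_m, half_h_m)`.
#' @export
camera_positions <- function(meta, ref_lat, ref_lon, rotation_deg = 0) {
  if (all(is.na(meta$lat)) || all(is.na(meta$lon))) {
    stopf("no image carries GPS coordinates")
  }
  loc <- latlon_to_local(meta$lat, meta$lon, ref_lat, ref_lon)
  xy <- rot2(rotation_deg) %*% rbind(loc$e, loc$n)
  data.frame(image_id = meta$image_id, e = xy[1, ], n = xy[2, ],
             half_w_m = meta$width * meta$gsd_cm_px / 200,
             half_h_m = meta$height * meta$gsd_cm_px / 200)
}

#' Assign the nearest covering image to every grid cell
#'
#' Each cell is assigned the image whose camera position is nearest the
#' cell center among those whose ground footprint fully covers the cell
#' rectangle; ties go to the lexicographically smaller image id.  Cells
#' with no covering footprint are left empty.
#'
#' @param grid a [build_grid()] result.
#' @param cams camera positions from [camera_positions()].
#' @return the grid with its `assignment` matrix filled.
#' @export
assign_images <- function(grid, cams) {
  eps <- 1e-9
  ord <- order(cams$image_id)
  cams <- cams[ord, , drop = FALSE]
  for (j in seq_len(grid$n_rows)) {
    for (i in seq_len(grid$n_cols)) {
      cx <- grid$centers_x[i]; cy <- grid$centers_y[j]
      cover <- abs(cams$e - cx) <= cams$half_w_m - grid$m_x / 2 + eps &
        abs(cams$n - cy) <= cams$half_h_m - grid$m_y / 2 + eps
      if (!any(cover)) next
      cand <- which(cover)
      d2 <- (cams$e[cand] - cx)^2 + (cams$n[cand] - cy)^2
      grid$assignment[j, i] <- cams$image_id[cand[which.min(d2)]]
    }
  }
  grid
}

#' Compose field-frame detections from the assigned grid
#'
#' For every assigned cell, the cell image's (row-horizontal, i.e. already
#' rotated) detections are converted from pixels to metres via the image
#' GSD, translated by the camera mosaic position, and kept only when they
#' fall inside the half-open cell rectangle.  Because cells partition the
#' mosaic plane, a head seen by several overlapping images is kept exactly
#' once -- from the image assigned to its cell.
#'
#' @param grid an assigned [build_grid()] result.
#' @param per_image named list from [detect_rows_images()] (rotated
#'   detections per image), or any named list of
#'   `list(detections = <rotated dets>)`.
#' @param meta image metadata (pixel geometry and GSD).
#' @param cams camera positions from [camera_positions()] (same mosaic
#'   rotation as used for the grid).
#' @return `data.frame(east_m, north_m, cell_i, cell_j, source_image,
#'   confidence[, head_id])` -- the field detection set.
#' @export
compose_field_detections <- function(grid, per_image, meta, cams) {
  out <- list()
  for (j in seq_len(grid$n_rows)) {
    for (i in seq_len(grid$n_cols)) {
      id <- grid$assignment[j, i]
      if (is.na(id)) next
      entry <- per_image[[id]]
      if (is.null(entry)) {
        stopf("no detections/rotation recorded for assigned image %s", id,
              class = "paniclepipe_linkage_error")
      }
      d <- entry$detections
      if (is.null(d) || !nrow(d)) next
      rec <- meta[meta$image_id == id, , drop = FALSE]
      if (!nrow(rec)) {
        stopf("no metadata for assigned image %s", id,
              class = "paniclepipe_linkage_error")
      }
      cam <- cams[cams$image_id == id, , drop = FALSE]
      s <- rec$gsd_cm_px / 100
      ctr <- det_centers(d)
      e <- cam$e + (ctr$x - rec$width / 2) * s
      n <- cam$n - (ctr$y - rec$height / 2) * s
      keep <- e >= grid$centers_x[i] - grid$m_x / 2 &
        e < grid$centers_x[i] + grid$m_x / 2 &
        n >= grid$centers_y[j] - grid$m_y / 2 &
        n < grid$centers_y[j] + grid$m_y / 2
      if (!any(keep)) next
      fd <- data.frame(east_m = e[keep], north_m = n[keep],
                       cell_i = i, cell_j = j, source_image = id,
                       confidence = d$confidence[keep],
                       stringsAsFactors = FALSE)
      if (!is.null(d$head_id)) fd$head_id <- d$head_id[keep]
      out[[length(out) + 1]] <- fd
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(east_m = numeric(), north_m = numeric(),
               cell_i = integer(), cell_j = integer(),
               source_image = character(), confidence = numeric())
  rownames(res) <- NULL
  res
}

#' Default grid cell size
#'
#' 80% of the smallest image footprint side, satisfying the requirement
#' that cells be smaller than the image ground coverage.
#'
#' @param meta image metadata.
#' @param fraction footprint fraction (default 0.8).
#' @return cell size in metres.
#' @export
default_cell_size <- function(meta, fraction = 0.8) {
  fraction * min(c(meta$width, meta$height) *
                   rep(meta$gsd_cm_px, 2)) / 100
}

#' Compose a quasi-mosaic raster
#'
#' Fills each assigned cell of the canvas with the rotated, cropped patch
#' of its image raster (nearest-neighbour resampling).  Cells without a
#' raster are left blank with a warning.
#'
#' @param grid an assigned [build_grid()] result.
#' @param rasters named list (by image id) of numeric matrices
#'   (`height x width`, rows = y down).
#' @param meta image metadata.
#' @param cams camera positions (same rotation as the grid).
#' @param rotations named list (by image id) of rotation records from
#'   [rotate_to_horizontal()]; missing entries mean no rotation.
#' @param canvas_cm_px canvas scale, cm per canvas pixel.
#' @return `list(canvas, scale_cm_px, extent)`; canvas rows run from the
#'   north edge down.
#' @export
compose_mosaic_raster <- function(grid, rasters, meta, cams,
                                  rotations = list(), canvas_cm_px = 1) {
  s_can <- canvas_cm_px / 100
  Wc <- ceiling((grid$extent[2] - grid$extent[1]) / s_can)
  Hc <- ceiling((grid$extent[4] - grid$extent[3]) / s_can)
  canvas <- matrix(0, Hc, Wc)
  for (j in seq_len(grid$n_rows)) {
    for (i in seq_len(grid$n_cols)) {
      id <- grid$assignment[j, i]
      if (is.na(id)) next
      img <- rasters[[id]]
      if (is.null(img)) {
        warning(sprintf("no raster for assigned image %s; cell left blank",
                        id))
        next
      }
      rec <- meta[meta$image_id == id, , drop = FALSE]
      cam <- cams[cams$image_id == id, , drop = FALSE]
      theta <- if (!is.null(rotations[[id]])) {
        rotations[[id]]$theta_deg
      } else 0
      s_img <- rec$gsd_cm_px / 100
      ## canvas pixel block of this cell
      c0 <- round((grid$centers_x[i] - grid$m_x / 2 - grid$extent[1]) / s_can)
      c1 <- round((grid$centers_x[i] + grid$m_x / 2 - grid$extent[1]) / s_can)
      r0 <- round((grid$extent[4] - (grid$centers_y[j] + grid$m_y / 2)) /
                    s_can)
      r1 <- round((grid$extent[4] - (grid$centers_y[j] - grid$m_y / 2)) /
                    s_can)
      cols <- (c0 + 1):min(c1, Wc)
      rws <- (r0 + 1):min(r1, Hc)
      e <- grid$extent[1] + (cols - 0.5) * s_can
      n <- grid$extent[4] - (rws - 0.5) * s_can
      ## rotated-image coordinates, then undo the horizontal correction
      vx <- outer(rep(1, length(rws)), (e - cam$e) / s_img)
      vy <- outer(-(n - cam$n) / s_img, rep(1, length(cols)))
      phi <- deg2rad(theta)  # inverse of the -theta correction
      xi <- cos(phi) * vx - sin(phi) * vy + rec$width / 2
      yi <- sin(phi) * vx + cos(phi) * vy + rec$height / 2
      px <- round(xi + 0.5); py <- round(yi + 0.5)
      ok <- px >= 1 & px <= ncol(img) & py >= 1 & py <= nrow(img)
      patch <- matrix(0, length(rws), length(cols))
      patch[ok] <- img[cbind(py[ok], px[ok])]
      canvas[rws, cols] <- patch
    }
  }
  list(canvas = canvas, scale_cm_px = canvas_cm_px, extent = grid$extent)
}

#' One-call quasi-mosaic composition
#'
#' Convenience driver used by the pipeline: computes the global mosaic
#' rotation (mean per-image dominant direction), projects cameras, builds
#' the grid over the union of footprints, assigns images and composes the
#' field detection set.
#'
#' @param per_image result of [detect_rows_images()].
#' @param meta image metadata.
#' @param ref_lat,ref_lon field reference point (defaults to the mean
#'   camera GPS).
#' @param cell_m cell size in metres (default [default_cell_size()]).
#' @param extent_local optional `c(xmin, xmax, ymin, ymax)` in metres of
#'   the local (east/north) frame over which to grid; rotated into the
#'   mosaic frame internally.  Default: the camera hull.
#' @return `list(grid, cams, field_detections, rotation_deg)`.
#' @export
quasi_mosaic <- function(per_image, meta, ref_lat = NULL, ref_lon = NULL,
                         cell_m = NULL, extent_local = NULL) {
  ref_lat <- ref_lat %||% mean(meta$lat)
  ref_lon <- ref_lon %||% mean(meta$lon)
  thetas <- vapply(per_image, function(e) e$theta_deg %||% NA_real_, 0)
  theta_bar <- if (all(is.na(thetas))) 0 else mean(thetas, na.rm = TRUE)
  ## images with no direction estimate get the field consensus
  for (id in names(per_image)) {
    if (is.na(per_image[[id]]$theta_deg)) {
      rec <- meta[meta$image_id == id, , drop = FALSE]
      rot <- rotate_to_horizontal(per_image[[id]]$detections, rec,
                                  theta_bar)
      per_image[[id]]$theta_deg <- theta_bar
      per_image[[id]]$rotation <- rot$rotation
      per_image[[id]]$detections <- rot$detections
    }
  }
  cams <- camera_positions(meta, ref_lat, ref_lon, rotation_deg = theta_bar)
  cell_m <- cell_m %||% default_cell_size(meta)
  extent <- if (!is.null(extent_local)) {
    corners <- rot2(theta_bar) %*%
      rbind(extent_local[c(1, 2, 1, 2)], extent_local[c(3, 3, 4, 4)])
    c(range(corners[1, ]), range(corners[2, ]))
  } else {
    c(min(cams$e), max(cams$e), min(cams$n), max(cams$n))
  }
  grid <- build_grid(extent, cell_m)
  grid <- assign_images(grid, cams)
  fd <- compose_field_detections(grid, per_image, meta, cams)
  list(grid = grid, cams = cams, field_detections = fd,
       rotation_deg = theta_bar)
}
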