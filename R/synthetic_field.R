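## Synthetic sorghum-field simulator: parallel planting rows, Poisson head
## placement with carved-out gaps, simulated overlapping camera captures
## with GPS, and a configurable detector-noise model.  Every downstream
## stage of the pipeline can be exercised against the ground truth this
## module records.

#' Field configuration
#'
#' Describes a rectangular field of parallel planting rows.  Defaults
#' follow common sorghum agronomy: 75 cm row spacing and 6 heads per
#' row-metre (a planting density of 80 k plants/ha at 75 cm spacing is
#' 6 plants per metre of row).
#'
#' @param n_rows number of planting rows.
#' @param row_spacing_m perpendicular distance between adjacent rows, m.
#' @param row_length_m sown length of each row, m.
#' @param heads_per_m Poisson intensity of head placement along each row
#'   (heads per metre); scalar or one value per row.
#' @param orientation_deg row direction, degrees counter-clockwise from
#'   local east.
#' @param cross_jitter_sd_m Gaussian s.d. of each head's perpendicular
#'   offset from its row line, m (default 2 cm).
#' @param head_diameter_cm apparent head diameter, cm (sets simulated
#'   bounding-box size).
#' @param gaps optional `data.frame(row, start_m, end_m)` of unsown spans
#'   carved out of rows (along-row coordinates).
#' @param origin_lat,origin_lon GPS anchor of the field local frame
#'   (row 1 starts at local (0, 0)).
#' @param seed integer seed; regeneration with the same configuration is
#'   bit-identical.
#' @return a `field_config` list.
#' @export
field_config <- function(n_rows = 8, row_spacing_m = 0.75, row_length_m = 10,
                         heads_per_m = 6, orientation_deg = 0,
                         cross_jitter_sd_m = 0.02, head_diameter_cm = 10,
                         gaps = NULL, origin_lat = -27.45,
                         origin_lon = 151.53, seed = 1L) {
  if (!is_pos(row_spacing_m) || !is_pos(row_length_m) || n_rows < 1) {
    stopf("field geometry must be positive", class = "paniclepipe_config_error")
  }
  if (any(heads_per_m < 0) || cross_jitter_sd_m < 0) {
    stopf("densities and jitter must be >= 0",
          class = "paniclepipe_config_error")
  }
  if (!is.null(gaps)) {
    stopifnot(all(c("row", "start_m", "end_m") %in% names(gaps)))
  }
  structure(list(n_rows = as.integer(n_rows), row_spacing_m = row_spacing_m,
                 row_length_m = row_length_m,
                 heads_per_m = rep_len(heads_per_m, n_rows),
                 orientation_deg = orientation_deg,
                 cross_jitter_sd_m = cross_jitter_sd_m,
                 head_diameter_cm = head_diameter_cm, gaps = gaps,
                 origin_lat = origin_lat, origin_lon = origin_lon,
                 seed = as.integer(seed)),
            class = "field_config")
}

#' Generate a ground-truth field
#'
#' Heads are placed along each row by a homogeneous 1-D Poisson process of
#' the configured intensity, given a Gaussian perpendicular jitter, and
#' then removed from any configured gap span.  The field local frame has
#' row 1 starting at (0, 0); rows advance along `orientation_deg` and are
#' stacked at `row_spacing_m` in the perpendicular direction.
#'
#' @param config a [field_config()].
#' @return a `field_truth` list with elements `rows` (one line per row:
#'   `row`, `cross_m`, `length_m`, `orientation_deg`), `heads`
#'   (`head_id`, `row`, `along_m`, `cross_m`, `x_m`, `y_m`), `gaps`, and
#'   the generating `config`.
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  with_seed(config$seed, {
    rows <- data.frame(row = seq_len(config$n_rows),
                       cross_m = (seq_len(config$n_rows) - 1) *
                         config$row_spacing_m,
                       length_m = config$row_length_m,
                       orientation_deg = config$orientation_deg)
    heads <- vector("list", config$n_rows)
    for (r in seq_len(config$n_rows)) {
      lam <- config$heads_per_m[r]
      n <- if (lam > 0) stats::rpois(1, lam * config$row_length_m) else 0L
      if (n == 0) {
        heads[[r]] <- data.frame(row = integer(), along_m = numeric(),
                                 cross_m = numeric())
        next
      }
      along <- sort(stats::runif(n, 0, config$row_length_m))
      cross <- rows$cross_m[r] +
        stats::rnorm(n, 0, config$cross_jitter_sd_m)
      keep <- rep(TRUE, n)
      if (!is.null(config$gaps)) {
        g <- config$gaps[config$gaps$row == r, , drop = FALSE]
        for (k in seq_len(nrow(g))) {
          keep <- keep & !(along > g$start_m[k] & along < g$end_m[k])
        }
      }
      heads[[r]] <- data.frame(row = r, along_m = along[keep],
                               cross_m = cross[keep])
    }
    heads <- do.call(rbind, heads)
    th <- deg2rad(config$orientation_deg)
    heads$x_m <- cos(th) * heads$along_m - sin(th) * heads$cross_m
    heads$y_m <- sin(th) * heads$along_m + cos(th) * heads$cross_m
    heads <- cbind(head_id = seq_len(nrow(heads)), heads)
    rownames(heads) <- NULL
    structure(list(rows = rows, heads = heads, gaps = config$gaps,
                   config = config),
              class = "field_truth")
  })
}

#' Capture configuration
#'
#' Camera and flight parameters for simulated nadir captures.  The ground
#' footprint of an image is `width * gsd / 100` by `height * gsd / 100`
#' metres.
#'
#' @param gsd_cm_px ground sampling distance, cm/px.
#' @param image_w_px,image_h_px image size in pixels.
#' @param overlap_fraction fraction in `[0, 1)` by which consecutive
#'   footprints overlap (sets the flight-line stride when a flight path is
#'   generated automatically).
#' @param flight_path optional `data.frame(lat, lon)` of camera positions;
#'   when `NULL`, [make_flight_path()] lays a serpentine grid over the
#'   field.
#' @param yaw_deg camera yaw (0 = image x axis pointing east).
#' @param margin_m extra margin around the field covered by the automatic
#'   flight path, m.
#' @return a `capture_config` list.
#' @export
capture_config <- function(gsd_cm_px = 0.5, image_w_px = 1600,
                           image_h_px = 1600, overlap_fraction = 0.6,
                           flight_path = NULL, yaw_deg = 0, margin_m = 2) {
  if (!is_pos(gsd_cm_px) || !is_pos(image_w_px) || !is_pos(image_h_px)) {
    stopf("zero-area footprint", class = "paniclepipe_config_error")
  }
  if (!(overlap_fraction >= 0 && overlap_fraction < 1)) {
    stopf("overlap_fraction must be in [0, 1)",
          class = "paniclepipe_config_error")
  }
  structure(list(gsd_cm_px = gsd_cm_px, image_w_px = image_w_px,
                 image_h_px = image_h_px,
                 overlap_fraction = overlap_fraction,
                 flight_path = flight_path, yaw_deg = yaw_deg,
                 margin_m = margin_m),
            class = "capture_config")
}

#' Serpentine flight path covering a field
#'
#' Lays camera positions on a regular lattice whose stride is
#' `footprint * (1 - overlap_fraction)`, with camera centers spanning the
#' field bounding box plus a margin, in boustrophedon order.  A margin of
#' at least half the mosaic cell size guarantees that every cell touching
#' the field is fully covered by its nearest image.
#'
#' @param truth a `field_truth`.
#' @param cap a [capture_config()].
#' @return `data.frame(lat, lon)` of camera positions.
#' @export
make_flight_path <- function(truth, cap) {
  fw <- cap$image_w_px * cap$gsd_cm_px / 100
  fh <- cap$image_h_px * cap$gsd_cm_px / 100
  ext <- field_extent(truth, margin_m = cap$margin_m)
  sx <- max(fw * (1 - cap$overlap_fraction), 1e-6)
  sy <- max(fh * (1 - cap$overlap_fraction), 1e-6)
  xs <- seq(ext[1], ext[2] + sx, by = sx)
  ys <- seq(ext[3], ext[4] + sy, by = sy)
  pos <- do.call(rbind, lapply(seq_along(ys), function(j) {
    x <- if (j %% 2 == 1) xs else rev(xs)
    data.frame(e = x, n = ys[j])
  }))
  local_to_latlon(pos$e, pos$n, truth$config$origin_lat,
                  truth$config$origin_lon)
}

#' Field bounding box in local metres
#'
#' @param truth a `field_truth`.
#' @param margin_m margin added on every side.
#' @return numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
field_extent <- function(truth, margin_m = 0) {
  th <- deg2rad(truth$config$orientation_deg)
  along <- c(0, truth$config$row_length_m)
  cross <- range(truth$rows$cross_m)
  corners <- expand.grid(a = along, c = cross)
  x <- cos(th) * corners$a - sin(th) * corners$c
  y <- sin(th) * corners$a + cos(th) * corners$c
  c(min(x) - margin_m, max(x) + margin_m, min(y) - margin_m, max(y) + margin_m)
}

#' Simulate camera captures of a field
#'
#' Every head whose ground position falls inside an image footprint yields
#' one ground-truth bounding box of side `head_diameter_cm / gsd` pixels in
#' that image's pixel frame (origin top-left, x right, y down); heads in
#' overlap regions appear in every covering image.  Camera GPS is stored
#' per image.
#'
#' @param truth a `field_truth`.
#' @param cap a [capture_config()].
#' @return `list(meta, detections)`: an image-metadata table (see
#'   [image_records()]) and the ground-truth detections with a `head_id`
#'   provenance column and confidence 1.
#' @export
capture_images <- function(truth, cap) {
  stopifnot(inherits(truth, "field_truth"), inherits(cap, "capture_config"))
  path <- cap$flight_path %||% make_flight_path(truth, cap)
  pos <- latlon_to_local(path$lat, path$lon, truth$config$origin_lat,
                         truth$config$origin_lon)
  fw <- cap$image_w_px * cap$gsd_cm_px / 100
  fh <- cap$image_h_px * cap$gsd_cm_px / 100
  ext <- field_extent(truth)
  hit <- pos$e + fw / 2 > ext[1] & pos$e - fw / 2 < ext[2] &
    pos$n + fh / 2 > ext[3] & pos$n - fh / 2 < ext[4]
  if (!any(hit)) stopf("no footprint intersects the field",
                       class = "paniclepipe_config_error")
  pos <- pos[hit, , drop = FALSE]
  ids <- sprintf("img%04d", seq_len(nrow(pos)))
  gps <- local_to_latlon(pos$e, pos$n, truth$config$origin_lat,
                         truth$config$origin_lon)
  meta <- image_records(ids, cap$image_w_px, cap$image_h_px, cap$gsd_cm_px,
                        gps$lat, gps$lon, cap$yaw_deg)
  s <- cap$gsd_cm_px / 100  # metres per pixel
  side <- truth$config$head_diameter_cm / cap$gsd_cm_px
  dets <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    xp <- (truth$heads$x_m - pos$e[i]) / s + cap$image_w_px / 2
    yp <- (pos$n[i] - truth$heads$y_m) / s + cap$image_h_px / 2
    keep <- xp >= 0 & xp < cap$image_w_px & yp >= 0 & yp < cap$image_h_px
    if (!any(keep)) next
    ## boxes keep their full size even when the head sits at the image
    ## edge, so box centers invert exactly to field coordinates
    dets[[i]] <- detections(image_id = ids[i],
                            x_min = xp[keep] - side / 2,
                            y_min = yp[keep] - side / 2,
                            x_max = xp[keep] + side / 2,
                            y_max = yp[keep] + side / 2,
                            confidence = 1,
                            head_id = truth$heads$head_id[keep])
  }
  dets <- do.call(rbind, dets) %||% detections()
  rownames(dets) <- NULL
  list(meta = meta, detections = dets)
}

#' Detector-noise configuration
#'
#' Emulates the three error modes of a real detector: missed heads (false
#' negatives), spurious boxes (false positives placed uniformly over each
#' footprint), and localization jitter.  Confidence scores are drawn from
#' truncated normals in `[0, 1]`, with false positives drawn at a lower
#' mean so that precision-recall curves are non-degenerate.
#'
#' @param fp_rate_per_m2 expected false positives per square metre of
#'   footprint.
#' @param fn_prob probability in `[0, 1]` that a true box is dropped.
#' @param box_jitter_px_sd Gaussian s.d. of the box-center jitter, px.
#' @param conf_true,conf_false `(mean, sd)` of the confidence model for
#'   true and false boxes; `conf_true = NULL` leaves the input
#'   confidences untouched (exact identity when all rates are zero).
#' @param seed integer seed (deterministic corruption given the seed).
#' @return a `detector_noise` list.
#' @export
detector_noise <- function(fp_rate_per_m2 = 0, fn_prob = 0,
                           box_jitter_px_sd = 0, conf_true = c(0.9, 0.05),
                           conf_false = c(0.5, 0.15), seed = 1L) {
  if (fp_rate_per_m2 < 0 || fn_prob < 0 || fn_prob > 1 ||
      box_jitter_px_sd < 0) {
    stopf("noise rates outside their ranges",
          class = "paniclepipe_config_error")
  }
  structure(list(fp_rate_per_m2 = fp_rate_per_m2, fn_prob = fn_prob,
                 box_jitter_px_sd = box_jitter_px_sd,
                 conf_true = conf_true, conf_false = conf_false,
                 seed = as.integer(seed)),
            class = "detector_noise")
}

#' Corrupt ground-truth detections with detector noise
#'
#' Each ground-truth box is dropped with probability `fn_prob`; survivors
#' are translated by Gaussian jitter; false boxes are added at
#' `fp_rate_per_m2` over each image footprint.  Deterministic given the
#' noise seed.
#'
#' @param dets ground-truth detections.
#' @param noise a [detector_noise()].
#' @param meta image metadata (needed for footprint areas and false-box
#'   placement).
#' @return corrupted detection table; surviving true boxes keep their
#'   `head_id`, false positives get `head_id = NA`.
#' @export
corrupt_detections <- function(dets, noise, meta) {
  stopifnot(inherits(noise, "detector_noise"))
  with_seed(noise$seed, {
    out <- dets
    n <- nrow(out)
    if (n) {
      drop <- stats::runif(n) < noise$fn_prob
      out <- out[!drop, , drop = FALSE]
      m <- nrow(out)
      if (m && noise$box_jitter_px_sd > 0) {
        dx <- stats::rnorm(m, 0, noise$box_jitter_px_sd)
        dy <- stats::rnorm(m, 0, noise$box_jitter_px_sd)
        out$x_min <- out$x_min + dx; out$x_max <- out$x_max + dx
        out$y_min <- out$y_min + dy; out$y_max <- out$y_max + dy
      }
      if (m && !is.null(noise$conf_true)) {
        out$confidence <- rnorm_clamped(m, noise$conf_true[1],
                                        noise$conf_true[2])
      }
    }
    if (noise$fp_rate_per_m2 > 0) {
      side <- if (n) stats::median(dets$x_max - dets$x_min) else 20
      fps <- vector("list", nrow(meta))
      for (i in seq_len(nrow(meta))) {
        area <- (meta$width[i] * meta$gsd_cm_px[i] / 100) *
          (meta$height[i] * meta$gsd_cm_px[i] / 100)
        k <- stats::rpois(1, noise$fp_rate_per_m2 * area)
        if (k == 0) next
        cx <- stats::runif(k, side / 2, meta$width[i] - side / 2)
        cy <- stats::runif(k, side / 2, meta$height[i] - side / 2)
        fps[[i]] <- detections(image_id = meta$image_id[i],
                               x_min = cx - side / 2, y_min = cy - side / 2,
                               x_max = cx + side / 2, y_max = cy + side / 2,
                               confidence = rnorm_clamped(
                                 k, noise$conf_false[1], noise$conf_false[2]),
                               head_id = NA_integer_)
      }
      fps <- do.call(rbind, fps)
      if (!is.null(fps)) {
        if (is.null(out$head_id)) out$head_id <- NA_integer_
        out <- rbind(out, fps[names(out)])
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Render a simulated image raster
#'
#' Draws a uniform background plus filled elliptical blobs at every head
#' visible in the image.  Used for documentation figures and for
#' exercising reference blob counters; not a photorealistic canopy model.
#'
#' @param rec single image record (must carry GPS).
#' @param truth a `field_truth`.
#' @param background,value background and blob intensities.
#' @return numeric matrix `height x width` (rows = y, top first).
#' @export
render_image <- function(rec, truth, background = 0.15, value = 1) {
  m <- matrix(background, nrow = rec$height, ncol = rec$width)
  pos <- latlon_to_local(rec$lat, rec$lon, truth$config$origin_lat,
                         truth$config$origin_lon)
  s <- rec$gsd_cm_px / 100
  xp <- (truth$heads$x_m - pos$e) / s + rec$width / 2
  yp <- (pos$n - truth$heads$y_m) / s + rec$height / 2
  rx <- truth$config$head_diameter_cm / rec$gsd_cm_px / 2
  ry <- rx * 0.8
  keep <- xp >= -rx & xp < rec$width + rx & yp >= -ry & yp < rec$height + ry
  for (i in which(keep)) {
    cols <- max(1, floor(xp[i] - rx)):min(rec$width, ceiling(xp[i] + rx))
    rws <- max(1, floor(yp[i] - ry)):min(rec$height, ceiling(yp[i] + ry))
    if (!length(cols) || !length(rws)) next
    dx2 <- ((cols - 0.5 - xp[i]) / rx)^2
    dy2 <- ((rws - 0.5 - yp[i]) / ry)^2
    inside <- outer(dy2, dx2, `+`) <= 1
    m[rws, cols][inside] <- value
  }
  m
}

#' Per-row ground-truth head counts
#'
#' @param truth a `field_truth`.
#' @return `data.frame(row, count)`; the counts sum to the total head
#'   count.
#' @export
truth_row_counts <- function(truth) {
  tab <- table(factor(truth$heads$row, levels = truth$rows$row))
  data.frame(row = truth$rows$row, count = as.integer(tab))
}

#' Write a truth manifest
#'
#' JSON manifest of the generating configuration, row lines, head field
#' coordinates and gaps, sufficient to reconstruct every ground-truth
#' quantity used by the tests.
#'
#' @param truth a `field_truth`.
#' @param path output path.
#' @export
write_truth_manifest <- function(truth, path) {
  obj <- list(config = unclass(truth$config), rows = truth$rows,
              heads = truth$heads, gaps = truth$gaps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
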