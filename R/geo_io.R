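## Detection and image-metadata I/O, GSD calibration, image-normalization
## preprocessing, and the local planar (equirectangular) GPS projection.

#' Construct a detection table
#'
#' Detections are plain data frames, one bounding box per line, in the pixel
#' frame of their source image: origin at the top-left corner, x to the
#' right, y downward, boxes half-open `[min, max)`.
#'
#' @param image_id character identifier of the source image.
#' @param x_min,y_min,x_max,y_max box corners in pixels; `x_max > x_min`
#'   and `y_max > y_min` are required.
#' @param confidence detector confidence in `[0, 1]`; defaults to 1 for
#'   ground-truth boxes.
#' @param ... additional columns (e.g. a `head_id` provenance column from
#'   the synthetic simulator) recycled to the number of boxes.
#' @return a `data.frame` with at least the six canonical columns.
#' @seealso [det_centers()], [read_detections()], [write_detections()]
#' @export
detections <- function(image_id = character(), x_min = numeric(),
                       y_min = numeric(), x_max = numeric(),
                       y_max = numeric(), confidence = 1, ...) {
  n <- length(x_min)
  df <- data.frame(image_id = as.character(rep_len(image_id, n)),
                   x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   confidence = as.numeric(rep_len(confidence, n)),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_detections(df)
}

#' Validate a detection table
#'
#' Checks the box and confidence invariants and returns the table
#' unchanged; the index of the first offending record is reported.
#'
#' @param dets detection `data.frame` (see [detections()]).
#' @return `dets`, invisibly unchanged.
#' @export
validate_detections <- function(dets) {
  req <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  miss <- setdiff(req, names(dets))
  if (length(miss)) {
    stopf("detection table is missing column(s): %s",
          paste(miss, collapse = ", "), class = "paniclepipe_parse_error")
  }
  if (nrow(dets)) {
    bad <- which(!(dets$x_max > dets$x_min & dets$y_max > dets$y_min))
    if (length(bad)) {
      stopf("degenerate box (max <= min) at record %d", bad[1],
            class = "paniclepipe_parse_error")
    }
    badc <- which(dets$confidence < 0 | dets$confidence > 1 |
                    is.na(dets$confidence))
    if (length(badc)) {
      stopf("confidence outside [0, 1] at record %d", badc[1],
            class = "paniclepipe_parse_error")
    }
  }
  dets
}

#' Bounding-box centers
#'
#' @param dets detection table.
#' @return `data.frame` with columns `x`, `y` (pixels) and `id` (row index
#'   into `dets`, used as the point identifier by the row-fitting stage).
#' @export
det_centers <- function(dets) {
  data.frame(x = (dets$x_min + dets$x_max) / 2,
             y = (dets$y_min + dets$y_max) / 2,
             id = seq_len(nrow(dets)))
}

#' Construct an image-metadata table
#'
#' One record per image: pixel geometry, ground sampling distance and the
#' camera GPS position (WGS84, taken as the principal point at nadir).
#'
#' @param image_id character id.
#' @param width,height image size in pixels (positive).
#' @param gsd_cm_px ground sampling distance, cm per pixel.
#' @param lat,lon camera latitude/longitude in degrees.
#' @param yaw_deg optional camera yaw, degrees (default 0).
#' @return `data.frame` with one row per image.
#' @export
image_records <- function(image_id, width, height, gsd_cm_px, lat = NA_real_,
                          lon = NA_real_, yaw_deg = 0) {
  n <- length(image_id)
  df <- data.frame(image_id = as.character(image_id),
                   width = as.numeric(rep_len(width, n)),
                   height = as.numeric(rep_len(height, n)),
                   gsd_cm_px = as.numeric(rep_len(gsd_cm_px, n)),
                   lat = as.numeric(rep_len(lat, n)),
                   lon = as.numeric(rep_len(lon, n)),
                   yaw_deg = as.numeric(rep_len(yaw_deg, n)),
                   stringsAsFactors = FALSE)
  bad <- which(!(df$width > 0 & df$height > 0 & df$gsd_cm_px > 0))
  if (length(bad)) stopf("non-positive image geometry at record %d", bad[1])
  df
}

#' Ground sampling distance from a reference object
#'
#' Calibrates the GSD of an image from the apparent pixel width of a
#' reference object of known physical width (e.g. a 30 x 15 cm rectangle
#' laid in the field of view).
#'
#' @param ref_width_px apparent width of the reference object, pixels.
#' @param ref_width_cm physical width of the reference object, cm.
#' @return GSD in cm per pixel.
#' @examples
#' compute_gsd(120, 30)  # 0.25 cm/px
#' @export
compute_gsd <- function(ref_width_px, ref_width_cm) {
  if (!is_pos(ref_width_px) || !is_pos(ref_width_cm)) {
    stopf("reference widths must be positive")
  }
  ref_width_cm / ref_width_px
}

#' Center-crop an image record and its detections
#'
#' Removes `edge_fraction` of each dimension from each side (the central
#' `1 - 2 * edge_fraction` of the image is retained), the usual guard
#' against lens edge distortion.  Detections whose centers fall outside
#' the retained window are dropped; survivors are clipped to the window
#' and shifted to the new origin.
#'
#' @param rec single image record (one-row data frame, see
#'   [image_records()]).
#' @param dets detections belonging to `rec` (may be empty).
#' @param edge_fraction fraction in `[0, 0.5)` removed from each side;
#'   default 0.10.
#' @return `list(record, detections)` with updated geometry.
#' @export
center_crop <- function(rec, dets, edge_fraction = 0.10) {
  if (!(edge_fraction >= 0 && edge_fraction < 0.5)) {
    stopf("edge_fraction must be in [0, 0.5)")
  }
  W <- rec$width; H <- rec$height
  x0 <- round(W * edge_fraction); y0 <- round(H * edge_fraction)
  newW <- W - 2 * x0; newH <- H - 2 * y0
  if (nrow(dets)) {
    ctr <- det_centers(dets)
    keep <- ctr$x >= x0 & ctr$x < W - x0 & ctr$y >= y0 & ctr$y < H - y0
    dets <- dets[keep, , drop = FALSE]
    dets$x_min <- pmax(dets$x_min - x0, 0)
    dets$y_min <- pmax(dets$y_min - y0, 0)
    dets$x_max <- pmin(dets$x_max - x0, newW)
    dets$y_max <- pmin(dets$y_max - y0, newH)
    rownames(dets) <- NULL
  }
  rec$width <- newW; rec$height <- newH
  list(record = rec, detections = dets)
}

#' Rescale an image record and its detections to a target GSD
#'
#' Applies the scale factor `s = G / target_gsd` to all pixel coordinates
#' and dimensions so that the physical ground positions (`px * G`) are
#' preserved while the nominal GSD becomes `target_gsd`.
#'
#' @param rec single image record.
#' @param dets detections belonging to `rec`.
#' @param target_gsd target ground sampling distance, cm/px.
#' @return `list(record, detections)`.
#' @export
rescale_to_gsd <- function(rec, dets, target_gsd) {
  if (!is_pos(target_gsd) || !is_pos(rec$gsd_cm_px)) {
    stopf("GSDs must be positive")
  }
  s <- rec$gsd_cm_px / target_gsd
  if (nrow(dets)) {
    for (col in c("x_min", "y_min", "x_max", "y_max")) {
      dets[[col]] <- dets[[col]] * s
    }
  }
  rec$width <- rec$width * s
  rec$height <- rec$height * s
  rec$gsd_cm_px <- target_gsd
  list(record = rec, detections = dets)
}

#' Read detections from disk
#'
#' Two dialects are supported: a flat CSV with header
#' `image_id,x_min,y_min,x_max,y_max,confidence` (extra columns are
#' preserved), and COCO-style JSON (`images` / `annotations` /
#' `categories`, with `bbox = [x, y, w, h]` converted to the internal
#' corner form and `score` mapped to `confidence`).
#'
#' @param path file path.
#' @param format `"csv"`, `"coco"`, or `"auto"` (by file extension).
#' @return detection `data.frame`.
#' @export
read_detections <- function(path, format = c("auto", "csv", "coco")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) {
      return(detections())
    }
    df$image_id <- as.character(df$image_id)
    return(validate_detections(df))
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ann <- obj$annotations
  if (is.null(ann) || NROW(ann) == 0) return(detections())
  imgs <- obj$images
  id_map <- stats::setNames(as.character(imgs$file_name %||% imgs$id),
                            as.character(imgs$id))
  bbox <- do.call(rbind, ann$bbox)
  detections(image_id = unname(id_map[as.character(ann$image_id)]),
             x_min = bbox[, 1], y_min = bbox[, 2],
             x_max = bbox[, 1] + bbox[, 3], y_max = bbox[, 2] + bbox[, 4],
             confidence = ann$score %||% 1)
}

#' Write detections to disk
#'
#' Inverse of [read_detections()]; the write/read round trip is lossless
#' on the data model (CSV additionally preserves extra columns).
#'
#' @param dets detection table.
#' @param path output path.
#' @param format `"csv"`, `"coco"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path, format = c("auto", "csv", "coco")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco" else "csv"
  }
  validate_detections(dets)
  if (format == "csv") {
    utils::write.csv(dets, path, row.names = FALSE)
    return(invisible(path))
  }
  ids <- unique(dets$image_id)
  images <- data.frame(id = seq_along(ids), file_name = ids,
                       stringsAsFactors = FALSE)
  idx <- match(dets$image_id, ids)
  ann <- lapply(seq_len(nrow(dets)), function(i) {
    list(id = i, image_id = images$id[idx[i]], category_id = 1L,
         bbox = c(dets$x_min[i], dets$y_min[i],
                  dets$x_max[i] - dets$x_min[i],
                  dets$y_max[i] - dets$y_min[i]),
         score = dets$confidence[i])
  })
  obj <- list(images = images, annotations = ann,
              categories = data.frame(id = 1L, name = "head"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write image metadata
#'
#' Flat CSV with header `image_id,width,height,gsd_cm_px,lat,lon[,yaw_deg]`.
#'
#' @param path file path.
#' @return `read_image_meta` returns the metadata `data.frame`.
#' @export
read_image_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "width", "height", "gsd_cm_px", "lat", "lon")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stopf("metadata file missing column(s): %s", paste(miss, collapse = ", "),
          class = "paniclepipe_parse_error")
  }
  if (is.null(df$yaw_deg)) df$yaw_deg <- 0
  df$image_id <- as.character(df$image_id)
  df
}

#' @rdname read_image_meta
#' @param meta metadata `data.frame` (see [image_records()]).
#' @export
write_image_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Local planar projection of GPS coordinates
#'
#' Equirectangular projection about a field reference point: for fields
#' spanning well under a kilometre the curvature error is negligible.
#' `x = R cos(ref_lat) * dlon`, `y = R * dlat` with `R = 6,371,000` m.
#'
#' @param lat,lon points to project, degrees WGS84.
#' @param ref_lat,ref_lon reference point, degrees.
#' @return `latlon_to_local`: `data.frame(e, n)` in metres east/north of
#'   the reference; `local_to_latlon`: `data.frame(lat, lon)`.
#' @export
latlon_to_local <- function(lat, lon, ref_lat, ref_lon) {
  if (any(abs(lat) > 90) || abs(ref_lat) > 90) stopf("|lat| must be <= 90")
  R <- 6371000
  data.frame(e = R * cos(deg2rad(ref_lat)) * deg2rad(lon - ref_lon),
             n = R * deg2rad(lat - ref_lat))
}

#' @rdname latlon_to_local
#' @param e,n local coordinates in metres east/north of the reference.
#' @export
local_to_latlon <- function(e, n, ref_lat, ref_lon) {
  R <- 6371000
  data.frame(lat = ref_lat + rad2deg(n / R),
             lon = ref_lon + rad2deg(e / (R * cos(deg2rad(ref_lat)))))
}

#' Blur-matching sigma between two GSDs
#'
#' Heuristic Gaussian sigma (in pixels of the source image) used to soften
#' a high-resolution image so its texture roughly matches imagery at a
#' coarser GSD before running a detector trained on the latter.
#'
#' @param source_gsd,target_gsd GSDs in cm/px, `target_gsd >= source_gsd`.
#' @return sigma in source pixels.
#' @export
gsd_blur_sigma <- function(source_gsd, target_gsd) {
  if (!is_pos(source_gsd) || !is_pos(target_gsd)) stopf("GSDs must be positive")
  target_gsd / source_gsd
}

#' Gaussian-blur a raster matrix
#'
#' Separable Gaussian smoothing with edge renormalization (kernel weights
#' falling outside the raster are redistributed).  Operates on plain
#' numeric matrices; used only for raster fixtures and blur matching.
#'
#' @param m numeric matrix (rows = y, columns = x).
#' @param sigma Gaussian sigma in pixels.
#' @return blurred matrix of the same dimensions.
#' @export
blur_raster <- function(m, sigma) {
  if (sigma <= 0) return(m)
  g <- gaussian_kernel_1d(sigma)
  conv2_sep(m, g) / conv2_sep(matrix(1, nrow(m), ncol(m)), g)
}
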