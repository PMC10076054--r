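## Head-density statistics: per-row linear density and per-image areal
## density, along-row gap records, 1-D moving-sum row profiles, and the
## field-wide moving-sum density map with sum-one Gaussian smoothing.

#' Row head density
#'
#' `D_r = C_r / (W * G)` in heads per cm of row, reported x100 as heads
#' per metre.
#'
#' @param c_r head count along the row.
#' @param w_px row length in pixels (image width when the row traverses
#'   the image, otherwise the row's inlier x-span).
#' @param gsd_cm_px GSD in cm/px.
#' @return density in heads/m.
#' @examples
#' row_density(10, 400, 0.25)  # 10 heads/m
#' @export
row_density <- function(c_r, w_px, gsd_cm_px) {
  if (!is_pos(w_px) || !is_pos(gsd_cm_px)) stopf("W and G must be positive")
  if (any(c_r < 0)) stopf("counts must be >= 0")
  c_r / (w_px * gsd_cm_px) * 100
}

#' Image head density
#'
#' `D_i = C_i / (W * H * G^2)` in heads per cm^2, reported x10^4 as heads
#' per square metre.
#'
#' @param c_i head count across the image.
#' @param w_px,h_px image size in pixels.
#' @param gsd_cm_px GSD in cm/px.
#' @return density in heads/m^2.
#' @examples
#' image_density(5, 400, 400, 0.25)  # 5 heads/m^2 over a 1 m^2 image
#' @export
image_density <- function(c_i, w_px, h_px, gsd_cm_px) {
  if (!is_pos(w_px) || !is_pos(h_px) || !is_pos(gsd_cm_px)) {
    stopf("W, H and G must be positive")
  }
  if (any(c_i < 0)) stopf("counts must be >= 0")
  c_i / (w_px * h_px * gsd_cm_px^2) * 1e4
}

#' Detect along-row gaps
#'
#' Scans the consecutive differences of the sorted along-row positions,
#' including the distances from the row-span edges, and reports every span
#' longer than the threshold (default 50 cm) as a gap.  An empty row whose
#' span exceeds the threshold is one whole-span gap.
#'
#' @param pos_cm along-row head positions in cm (any order).
#' @param span_cm numeric `c(start, end)` of the row span, cm.
#' @param threshold_cm minimum reported gap length (default 50).
#' @return `data.frame(start_cm, end_cm, length_cm)`.
#' @export
detect_gaps <- function(pos_cm, span_cm, threshold_cm = 50) {
  bounds <- c(span_cm[1], sort(pos_cm), span_cm[2])
  len <- diff(bounds)
  idx <- which(len > threshold_cm)
  data.frame(start_cm = bounds[idx], end_cm = bounds[idx + 1],
             length_cm = len[idx])
}

#' Normalized 1-D Gaussian kernel
#'
#' @param sigma Gaussian sigma in sample units.
#' @param size odd kernel length; default covers +/- 3 sigma.
#' @return numeric vector summing to 1.
#' @export
gaussian_kernel_1d <- function(sigma, size = 2 * ceiling(3 * sigma) + 1) {
  if (size %% 2 == 0) stopf("kernel size must be odd")
  r <- (size - 1) / 2
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  g / sum(g)
}

## separable same-size convolution of a matrix with a 1-D kernel applied
## along both dimensions (zero padding; callers renormalize edges)
conv1_cols <- function(m, g) {
  r <- (length(g) - 1) / 2
  H <- nrow(m)
  mp <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- stats::filter(mp, g, method = "convolution", sides = 2)
  matrix(out, nrow(mp), ncol(m))[(r + 1):(r + H), , drop = FALSE]
}

conv2_sep <- function(m, g) {
  t(conv1_cols(t(conv1_cols(m, g)), g))
}

#' One-dimensional moving-sum row profile
#'
#' Head count in a sliding `window_cm` window at 1 cm steps along the row,
#' expressed as heads per metre (windows truncated at the row ends are
#' renormalized by their covered fraction), then smoothed with a discrete
#' Gaussian normalized to sum 1.
#'
#' @param pos_cm along-row head positions, cm.
#' @param span_cm numeric `c(start, end)` of the row span, cm.
#' @param window_cm moving-window width, cm (default 100).
#' @param sigma_cm Gaussian sigma, cm (default 25).
#' @param step_cm profile step, cm (default 1).
#' @return `data.frame(pos_cm, density, raw_density)` in heads/m.
#' @export
row_profile <- function(pos_cm, span_cm, window_cm = 100, sigma_cm = 25,
                        step_cm = 1) {
  if (!is_pos(window_cm)) stopf("window must be positive")
  grid <- seq(span_cm[1], span_cm[2], by = step_cm)
  pos <- sort(pos_cm)
  lo <- pmax(grid - window_cm / 2, span_cm[1])
  hi <- pmin(grid + window_cm / 2, span_cm[2])
  cnt <- findInterval(hi, pos) - findInterval(lo - 1e-9, pos)
  raw <- cnt / ((hi - lo) / 100)
  g <- gaussian_kernel_1d(sigma_cm / step_cm)
  r <- (length(g) - 1) / 2
  pad <- function(x) c(rep(0, r), x, rep(0, r))
  sm <- stats::filter(pad(raw), g, method = "convolution", sides = 2)
  cov <- stats::filter(pad(rep(1, length(raw))), g, method = "convolution",
                       sides = 2)
  sm <- as.numeric(sm)[(r + 1):(r + length(raw))] /
    as.numeric(cov)[(r + 1):(r + length(raw))]
  data.frame(pos_cm = grid, density = sm, raw_density = raw)
}

## exact centered moving-window sum of a count matrix via integral image;
## window w covers offsets [-floor((w-1)/2), +floor(w/2)] in each axis
moving_sum_2d <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1, W + 1)
  cs <- matrix(if (H > 1) apply(m, 2, cumsum) else m, H, W)
  if (W > 1) cs <- matrix(t(apply(cs, 1, cumsum)), H, W)
  P[-1, -1] <- cs
  lo_off <- floor((w - 1) / 2); hi_off <- floor(w / 2)
  r_lo <- pmax(seq_len(H) - lo_off, 1); r_hi <- pmin(seq_len(H) + hi_off, H)
  c_lo <- pmax(seq_len(W) - lo_off, 1); c_hi <- pmin(seq_len(W) + hi_off, W)
  S <- P[r_hi + 1, c_hi + 1] - P[r_lo, c_hi + 1] -
    P[r_hi + 1, c_lo] + P[r_lo, c_lo]
  list(sum = S, coverage = outer(r_hi - r_lo + 1, c_hi - c_lo + 1) / w^2)
}

#' Field-wide head-density map
#'
#' Rasterizes the field detection centers at `scale_cm_px` (default 1 cm
#' per map pixel), computes the moving `window_px x window_px` sum with
#' stride 1 (100 px at 1 cm/px makes each window 1 m x 1 m, so the sum is
#' directly heads per square metre), renormalizes windows truncated at the
#' field boundary by their covered fraction, and optionally smooths with a
#' Gaussian kernel normalized to sum 1 (which preserves the physical
#' unit).
#'
#' @param field_dets field detection set from
#'   [compose_field_detections()] (columns `east_m`, `north_m`), or any
#'   data frame with those columns.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres; default is
#'   the detection bounding box.
#' @param window_px moving-window side in map pixels (default 100).
#' @param scale_cm_px map scale (default 1 cm/px).
#' @param smooth logical; apply the Gaussian smoothing.
#' @param sigma_px Gaussian sigma in map pixels (default `window_px / 6`).
#' @param kernel_size odd kernel side (default 101, i.e. radius 50 px; an
#'   even size would have no center pixel).
#' @return a `density_map` list: `density` (smoothed heads/m^2, rows from
#'   the north edge down), `raw_density`, `moving_sum` (integer counts per
#'   window before edge renormalization), `coverage`, `counts`, `kernel`,
#'   `extent`, `scale_cm_px`, `window_px`.
#' @export
field_density_map <- function(field_dets, extent = NULL, window_px = 100,
                              scale_cm_px = 1, smooth = TRUE,
                              sigma_px = window_px / 6, kernel_size = 101) {
  if (!is_pos(scale_cm_px) || !is_pos(window_px)) {
    stopf("scale and window must be positive")
  }
  e <- field_dets$east_m; n <- field_dets$north_m
  if (is.null(extent)) {
    extent <- if (length(e)) c(min(e), max(e), min(n), max(n)) else
      c(0, 1, 0, 1)
  }
  s <- scale_cm_px / 100
  W <- max(1L, ceiling((extent[2] - extent[1]) / s))
  H <- max(1L, ceiling((extent[4] - extent[3]) / s))
  counts <- matrix(0L, H, W)
  if (length(e)) {
    ci <- pmin(pmax(floor((e - extent[1]) / s), 0), W - 1) + 1
    rj <- pmin(pmax(floor((extent[4] - n) / s), 0), H - 1) + 1
    inb <- e >= extent[1] & e <= extent[2] & n >= extent[3] & n <= extent[4]
    tab <- table(factor(rj[inb], levels = seq_len(H)),
                 factor(ci[inb], levels = seq_len(W)))
    counts <- matrix(as.integer(tab), H, W)
  }
  ms <- moving_sum_2d(counts, window_px)
  win_m2 <- (window_px * s)^2
  raw <- ms$sum / (ms$coverage * win_m2)
  density <- raw
  kernel <- NULL
  if (smooth) {
    g <- gaussian_kernel_1d(sigma_px, kernel_size)
    kernel <- outer(g, g)
    density <- conv2_sep(raw, g) / conv2_sep(matrix(1, H, W), g)
  }
  structure(list(density = density, raw_density = raw,
                 moving_sum = ms$sum, coverage = ms$coverage,
                 counts = counts, kernel = kernel, extent = extent,
                 scale_cm_px = scale_cm_px, window_px = window_px),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density map: %d x %d px at %.1f cm/px, window %d px, range %.3f-%.3f heads/m^2\n",
    ncol(x$density), nrow(x$density), x$scale_cm_px, x$window_px,
    min(x$density), max(x$density)))
  invisible(x)
}

#' Per-image head-density statistics
#'
#' Assigns an image's detections to their nearest detected row and
#' derives the per-row counts, lengths, linear densities and gap records,
#' plus the whole-image count and areal density.  Row length uses the
#' image width when the row's inlier span traverses (>= 90% of) the
#' image, otherwise the inlier x-span; the choice is recorded in
#' `length_source`.
#'
#' @param dets the image's (row-horizontal) detections.
#' @param rec the image record.
#' @param rows the image's `row_set`.
#' @param gap_threshold_cm minimum reported gap, cm (default 50).
#' @return an `image_stats` list: `image_id`, `per_row`
#'   (`row, a, b, c_r, length_m, d_r, length_source`), `gaps`
#'   (`row, start_cm, end_cm, length_cm`), `c_i`, `d_i`.
#' @export
image_stats <- function(dets, rec, rows, gap_threshold_cm = 50) {
  G <- rec$gsd_cm_px
  c_i <- nrow(dets)
  d_i <- image_density(c_i, rec$width, rec$height, G)
  per_row <- data.frame(row = integer(), a = numeric(), b = numeric(),
                        c_r = integer(), length_m = numeric(),
                        d_r = numeric(), length_source = character())
  gaps <- data.frame(row = integer(), start_cm = numeric(),
                     end_cm = numeric(), length_cm = numeric())
  if (length(rows) && c_i) {
    asn <- assign_to_nearest_row(dets, rows)
    for (r in seq_along(rows)) {
      m <- rows[[r]]
      span_px <- diff(m$x_span) * sqrt(1 + m$a^2)
      traverses <- diff(m$x_span) >= 0.9 * rec$width
      len_px <- if (traverses) rec$width else span_px
      sel <- asn[asn$row == r, , drop = FALSE]
      c_r <- nrow(sel)
      per_row <- rbind(per_row, data.frame(
        row = r, a = m$a, b = m$b, c_r = c_r,
        length_m = len_px * G / 100,
        d_r = row_density(c_r, len_px, G),
        length_source = if (traverses) "image_width" else "x_span"))
      g <- detect_gaps(sel$along_px * G, c(0, span_px * G),
                       gap_threshold_cm)
      if (nrow(g)) gaps <- rbind(gaps, cbind(row = r, g))
    }
  }
  structure(list(image_id = rec$image_id, per_row = per_row, gaps = gaps,
                 c_i = c_i, d_i = d_i),
            class = "image_stats")
}

#' Write a density map to plain files
#'
#' The map values go to a headerless CSV; origin, scale and window
#' metadata go to a JSON sidecar; optionally a PNG heat map is rendered
#' when the `png` package is available.
#'
#' @param map a `density_map`.
#' @param path_csv,path_json,path_png output paths (`path_png = NULL`
#'   skips the render).
#' @export
write_density_map <- function(map, path_csv, path_json, path_png = NULL) {
  utils::write.table(map$density, path_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(extent_m = map$extent,
                            scale_cm_px = map$scale_cm_px,
                            window_px = map$window_px,
                            n_rows = nrow(map$density),
                            n_cols = ncol(map$density),
                            unit = "heads/m^2"),
                       path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_png) && requireNamespace("png", quietly = TRUE)) {
    v <- map$density / max(map$density, 1e-12)
    ## simple blue->yellow->red ramp
    rgb <- array(0, c(nrow(v), ncol(v), 3))
    rgb[, , 1] <- pmin(1, 2 * v)
    rgb[, , 2] <- pmin(1, 2 * (1 - abs(v - 0.5)))
    rgb[, , 3] <- pmin(1, 2 * (1 - v))
    png::writePNG(rgb, path_png)
  }
  invisible(path_csv)
}
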