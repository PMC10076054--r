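## Independent oracles and fixture builders shared by the tests.  Every
## oracle here is a deliberately naive re-implementation (loops, lm(),
## flood fill) kept separate from the package's fast paths.

## angle helpers for test assertions
rad2deg_test <- function(x) abs(x) * 180 / pi
angle_diff_test <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

## points on horizontal pixel-frame rows: spacing_px apart, Poisson or
## fixed count per row, Gaussian jitter; returns x, y, id, row
make_row_points <- function(n_rows, spacing_px, length_px, pts_per_row,
                            jitter_px = 0, slope = 0, seed = 1,
                            y0 = spacing_px) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_rows), function(r) {
    x <- sort(runif(pts_per_row, 0, length_px))
    y <- y0 + (r - 1) * spacing_px + slope * x +
      rnorm(pts_per_row, 0, jitter_px)
    data.frame(x = x, y = y, row = r)
  }))
  out$id <- seq_len(nrow(out))
  out
}

## exhaustive best-line-over-all-point-pairs RANSAC oracle: every pair
## defines a candidate; candidates with more than d additional inliers
## within perpendicular distance t are refitted with lm(); the best
## candidate has the largest inlier set, ties broken by the lower mean
## perpendicular residual; returns the best inlier id set (and all
## tied-best sets)
oracle_pair_lines <- function(pts, t, d) {
  n <- nrow(pts)
  best_err <- Inf
  best_size <- -1L
  best_sets <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- pts$x[j] - pts$x[i]
      if (abs(dx) < 1e-12) next
      a <- (pts$y[j] - pts$y[i]) / dx
      b <- pts$y[i] - a * pts$x[i]
      dist <- abs(a * pts$x - pts$y + b) / sqrt(a^2 + 1)
      also <- setdiff(which(dist < t), c(i, j))
      if (length(also) <= d) next
      idx <- c(i, j, also)
      if (length(idx) < best_size) next
      fit <- stats::lm(y ~ x, data = pts[idx, ])
      a2 <- unname(stats::coef(fit)[2]); b2 <- unname(stats::coef(fit)[1])
      err <- mean(abs(a2 * pts$x[idx] - pts$y[idx] + b2) / sqrt(a2^2 + 1))
      key <- sort(pts$id[idx])
      better <- length(idx) > best_size ||
        (length(idx) == best_size && err < best_err - 1e-12)
      tied <- length(idx) == best_size && abs(err - best_err) <= 1e-12
      if (better) {
        best_err <- err
        best_size <- length(idx)
        best_sets <- list(key)
      } else if (tied &&
                 !any(vapply(best_sets, identical, TRUE, key))) {
        best_sets <- c(best_sets, list(key))
      }
    }
  }
  list(err = best_err, size = best_size, sets = best_sets)
}

## exhaustive nearest-covering-image assignment oracle
oracle_assign <- function(grid, cams) {
  out <- matrix(NA_character_, grid$n_rows, grid$n_cols)
  for (j in seq_len(grid$n_rows)) {
    for (i in seq_len(grid$n_cols)) {
      cx <- grid$centers_x[i]; cy <- grid$centers_y[j]
      best_id <- NA_character_; best_d <- Inf
      for (k in seq_len(nrow(cams))) {
        covers <- abs(cams$e[k] - cx) <= cams$half_w_m[k] -
          grid$m_x / 2 + 1e-9 &&
          abs(cams$n[k] - cy) <= cams$half_h_m[k] - grid$m_y / 2 + 1e-9
        if (!covers) next
        dd <- (cams$e[k] - cx)^2 + (cams$n[k] - cy)^2
        if (dd < best_d - 1e-15 ||
            (abs(dd - best_d) <= 1e-15 &&
             !is.na(best_id) && cams$image_id[k] < best_id)) {
          best_d <- dd; best_id <- cams$image_id[k]
        }
      }
      out[j, i] <- best_id
    }
  }
  out
}

## direct double-loop moving-window density (same definition as
## field_density_map's raw map, evaluated naively)
oracle_moving_density <- function(counts, w, win_area_m2) {
  H <- nrow(counts); W <- ncol(counts)
  lo <- floor((w - 1) / 2); hi <- floor(w / 2)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    r <- max(1, i - lo):min(H, i + hi)
    for (j in seq_len(W)) {
      cc <- max(1, j - lo):min(W, j + hi)
      s <- sum(counts[r, cc])
      cov <- length(r) * length(cc) / w^2
      out[i, j] <- s / (cov * win_area_m2)
    }
  }
  out
}

## direct double-loop edge-renormalized Gaussian smoothing
oracle_gaussian_smooth <- function(m, kernel) {
  H <- nrow(m); W <- ncol(m)
  r <- (nrow(kernel) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    ri <- max(1, i - r):min(H, i + r)
    ki <- ri - i + r + 1
    for (j in seq_len(W)) {
      cj <- max(1, j - r):min(W, j + r)
      kj <- cj - j + r + 1
      kk <- kernel[ki, kj, drop = FALSE]
      out[i, j] <- sum(m[ri, cj] * kk) / sum(kk)
    }
  }
  out
}

## connected components (4-neighbour flood fill) of a thresholded raster
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(FALSE, H, W)
  comps <- 0L
  for (start in which(mask & !lab)) {
    if (lab[start]) next
    comps <- comps + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p]) next
      lab[p] <- TRUE
      i <- ((p - 1) %% H) + 1; j <- ((p - 1) %/% H) + 1
      for (q in c(if (i > 1) p - 1, if (i < H) p + 1,
                  if (j > 1) p - H, if (j < W) p + H)) {
        if (mask[q] && !lab[q]) stack <- c(stack, q)
      }
    }
  }
  comps
}

## single-camera capture configuration centred over a given local point
single_camera_cap <- function(truth, e, n, gsd = 0.25, w = 800, h = 800) {
  gps <- local_to_latlon(e, n, truth$config$origin_lat,
                         truth$config$origin_lon)
  capture_config(gsd_cm_px = gsd, image_w_px = w, image_h_px = h,
                 flight_path = gps)
}

## compact pipeline configuration for fast end-to-end tests
small_pipeline_config <- function(seed = 1, jitter = 0.02) {
  cfg <- default_config(seed = seed)
  cfg$field$n_rows <- 5
  cfg$field$row_length_m <- 6
  cfg$field$cross_jitter_sd_m <- jitter
  cfg$capture$image_w_px <- 1200
  cfg$capture$image_h_px <- 1200
  cfg$capture$overlap_fraction <- 0.65
  cfg$capture$margin_m <- 1.5
  cfg$rows$k <- 300
  cfg
}
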