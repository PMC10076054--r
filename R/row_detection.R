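## Iterative RANSAC planting-row detection.  Rows are lines y = a*x + b in
## the image pixel frame, fitted repeatedly with a generic RANSAC inner
## loop; each accepted model's inliers are removed from the point pool and
## the search repeats until too few points remain or no model reaches the
## minimum consensus.  Also implements the dominant-direction estimate on
## the densest sub-window, direction filtering, horizontal correction and
## nearest-row assignment.

#' RANSAC parameters
#'
#' @param n minimum sample size per candidate line (>= 2).
#' @param k maximum iterations per row.
#' @param t inlier residual threshold in pixels (perpendicular
#'   point-to-line distance).  When `NULL` it defaults to
#'   `0.15 * row_spacing_px` if the planting-row spacing in pixels is
#'   supplied, else 10 px.  The threshold must stay well below half the
#'   row spacing: under consensus-size model ranking an overly wide band
#'   lets a diagonal line crossing two rows collect more inliers than a
#'   true row.
#' @param d minimum number of additional inliers required to accept a
#'   candidate model (`d >= n`).
#' @param row_spacing_px optional known row spacing in pixels, used only
#'   for the default `t`.
#' @param seed optional integer seed threaded through all RANSAC sampling.
#' @return a `ransac_params` list.
#' @export
ransac_params <- function(n = 2, k = 500, t = NULL, d = 5,
                          row_spacing_px = NULL, seed = NULL) {
  if (is.null(t)) {
    t <- if (!is.null(row_spacing_px)) 0.15 * row_spacing_px else 10
  }
  if (n < 2 || k < 1 || t <= 0 || d < n) {
    stopf("invalid RANSAC parameters (need n >= 2, k >= 1, t > 0, d >= n)",
          class = "paniclepipe_config_error")
  }
  structure(list(n = as.integer(n), k = as.integer(k), t = t,
                 d = as.integer(d), seed = seed),
            class = "ransac_params")
}

#' Ordinary least-squares line fit
#'
#' Fits `y = a*x + b` by least squares of y on x.  Vertical or
#' single-point inputs raise a degenerate-fit condition which RANSAC
#' callers catch and resample.
#'
#' @param pts `data.frame` with columns `x`, `y` (pixels).
#' @return named numeric `c(a, b)`.
#' @export
fit_line <- function(pts) {
  if (nrow(pts) < 2) {
    stopf("need at least 2 points", class = "paniclepipe_degenerate_fit")
  }
  mx <- mean(pts$x); my <- mean(pts$y)
  sxx <- sum((pts$x - mx)^2)
  if (sxx < 1e-12) {
    stopf("vertical input: all x identical",
          class = "paniclepipe_degenerate_fit")
  }
  a <- sum((pts$x - mx) * (pts$y - my)) / sxx
  c(a = a, b = my - a * mx)
}

## perpendicular distance of points to the line y = a*x + b
perp_dist <- function(pts, a, b) {
  abs(a * pts$x - pts$y + b) / sqrt(a^2 + 1)
}

new_row_model <- function(a, b, ids, pts, err) {
  structure(list(a = unname(a), b = unname(b), inlier_ids = ids,
                 x_span = range(pts$x), mean_residual = err,
                 n_inliers = length(ids)),
            class = "row_model")
}

#' @export
print.row_model <- function(x, ...) {
  cat(sprintf("row: y = %.5f x + %.2f, %d inliers, x span [%.1f, %.1f]\n",
              x$a, x$b, x$n_inliers, x$x_span[1], x$x_span[2]))
  invisible(x)
}

#' Single-row RANSAC
#'
#' One run of the generic RANSAC inner loop: at each of up to `k`
#' iterations, `n` points are sampled, a line fitted, additional inliers
#' collected within the perpendicular threshold `t`, and if more than `d`
#' additional points agree the model is refitted on the union.  The best
#' model across iterations is the one with the largest consensus set,
#' ties broken by the lower mean perpendicular residual (consensus first:
#' scoring by residual alone rewards short, locally tight segments of a
#' row over the full row).  The sampled points count as inliers of the
#' accepted model even if they drift outside `t` after the refit,
#' mirroring their removal from the pool by the outer loop.
#'
#' @param pts `data.frame` with columns `x`, `y`, and optionally `id`
#'   (defaults to the row number).
#' @param params a [ransac_params()].
#' @return a `row_model`, or `NULL` when no iteration reached the `d`
#'   consensus (a valid outcome, not an error).
#' @export
ransac_single <- function(pts, params) {
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  N <- nrow(pts)
  if (N < params$n) return(NULL)
  x <- pts$x; y <- pts$y
  with_seed(params$seed, {
    best <- NULL
    best_err <- Inf
    best_size <- -1L
    for (iter in seq_len(params$k)) {
      samp <- sample.int(N, params$n)
      sx <- x[samp]; sy <- y[samp]
      mx <- mean(sx); sxx <- sum((sx - mx)^2)
      if (sxx < 1e-12) next  # degenerate (vertical) sample: resample
      my <- mean(sy)
      a <- sum((sx - mx) * (sy - my)) / sxx
      b <- my - a * mx
      inl <- abs(a * x - y + b) / sqrt(a^2 + 1) < params$t
      inl[samp] <- FALSE
      if (sum(inl) > params$d) {
        idx <- c(samp, which(inl))
        size <- length(idx)
        if (size < best_size) next
        ux <- x[idx]; uy <- y[idx]
        mx2 <- mean(ux); sxx2 <- sum((ux - mx2)^2)
        if (sxx2 < 1e-12) next
        my2 <- mean(uy)
        a2 <- sum((ux - mx2) * (uy - my2)) / sxx2
        b2 <- my2 - a2 * mx2
        err <- mean(abs(a2 * ux - uy + b2) / sqrt(a2^2 + 1))
        if (size > best_size || err < best_err) {
          best_err <- err
          best_size <- size
          best <- new_row_model(a2, b2, pts$id[idx],
                                data.frame(x = ux, y = uy), err)
        }
      }
    }
    best
  })
}

#' Detect all planting rows in a point set
#'
#' Iterative multi-row RANSAC: repeatedly runs [ransac_single()], removes
#' each accepted model's inliers from the data, and stops when fewer than
#' `n` points remain or no further model reaches the consensus `d`.  Rows
#' are returned sorted by intercept `b`.
#'
#' @param pts point `data.frame` (columns `x`, `y`, optional `id`);
#'   typically [det_centers()] of an image's detections.  Empty input is
#'   allowed and yields an empty row set.
#' @param params a [ransac_params()]; its `seed` governs the whole
#'   multi-row search.
#' @return list of `row_model` objects (class `row_set`).
#' @export
detect_rows <- function(pts, params = ransac_params()) {
  if (is.null(pts$id) && nrow(pts)) pts$id <- seq_len(nrow(pts))
  inner <- params
  inner$seed <- NULL
  with_seed(params$seed, {
    out <- list()
    remaining <- pts
    while (nrow(remaining) > params$n) {
      m <- ransac_single(remaining, inner)
      if (is.null(m)) break
      out[[length(out) + 1]] <- m
      remaining <- remaining[!(remaining$id %in% m$inlier_ids), ,
                             drop = FALSE]
    }
    if (length(out)) out <- out[order(vapply(out, `[[`, 0, "b"))]
    structure(out, class = "row_set")
  })
}

#' @export
print.row_set <- function(x, ...) {
  cat(sprintf("row set: %d rows\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

## densest ceil(W/3) x ceil(H/3) sliding window (stride W/10, H/10)
densest_window <- function(pts, W, H) {
  wx <- ceiling(W / 3); wy <- ceiling(H / 3)
  xs <- seq(0, max(W - wx, 0), by = max(W / 10, 1))
  ys <- seq(0, max(H - wy, 0), by = max(H / 10, 1))
  best <- c(0, 0); best_n <- -1L
  for (x0 in xs) for (y0 in ys) {
    nn <- sum(pts$x >= x0 & pts$x < x0 + wx & pts$y >= y0 & pts$y < y0 + wy)
    if (nn > best_n) { best_n <- nn; best <- c(x0, y0) }
  }
  pts[pts$x >= best[1] & pts$x < best[1] + wx &
        pts$y >= best[2] & pts$y < best[2] + wy, , drop = FALSE]
}

#' Dominant planting-row direction of an image
#'
#' Runs single-row RANSAC on the densest third-of-the-image sub-window
#' (the prevailing row there is taken as the field direction).  To remain
#' robust for near-vertical rows the fit is attempted in both axis orders
#' and the better-scoring model wins.
#'
#' @param dets detection table of one image (or a point `data.frame` with
#'   `x`, `y`).
#' @param rec the image record (for the window geometry).
#' @param params a [ransac_params()].
#' @return the dominant direction in degrees, in `(-90, 90]`, measured in
#'   the pixel frame (0 = horizontal rows).
#' @export
dominant_direction <- function(dets, rec, params = ransac_params()) {
  pts <- if (!is.null(dets$x_min)) det_centers(dets) else dets
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  if (nrow(pts) < params$n) {
    stopf("too few detections for a direction estimate",
          class = "paniclepipe_insufficient_data")
  }
  sub <- densest_window(pts, rec$width, rec$height)
  if (nrow(sub) < params$n) sub <- pts
  m1 <- ransac_single(sub, params)
  swapped <- data.frame(x = sub$y, y = sub$x, id = sub$id)
  m2 <- ransac_single(swapped, params)
  if (is.null(m1) && is.null(m2)) {
    stopf("no line reached the RANSAC consensus in the densest window",
          class = "paniclepipe_insufficient_data")
  }
  s1 <- if (is.null(m1)) -1L else m1$n_inliers
  s2 <- if (is.null(m2)) -1L else m2$n_inliers
  e1 <- if (is.null(m1)) Inf else m1$mean_residual
  e2 <- if (is.null(m2)) Inf else m2$mean_residual
  if (s1 > s2 || (s1 == s2 && e1 <= e2)) {
    norm_angle_deg(rad2deg(atan(m1$a)))
  } else {
    norm_angle_deg(90 - rad2deg(atan(m2$a)))
  }
}

#' Filter detected rows by the dominant direction
#'
#' Rows whose slope angle deviates from the dominant direction by more
#' than `tol_deg` are discarded; their points are returned to the pool
#' and one refit pass is run, keeping only refit rows that agree with the
#' direction.
#'
#' @param rows a `row_set` from [detect_rows()].
#' @param theta_deg dominant direction, degrees.
#' @param tol_deg angular tolerance (default 10).
#' @param pts the point set the rows were fitted on (needed for the refit
#'   pass; when `NULL` discarded rows are simply dropped).
#' @param params [ransac_params()] for the refit pass.
#' @return filtered `row_set`, sorted by intercept.
#' @export
filter_rows_by_direction <- function(rows, theta_deg, tol_deg = 10,
                                     pts = NULL, params = ransac_params()) {
  if (!length(rows)) return(rows)
  ang <- vapply(rows, function(m) rad2deg(atan(m$a)), 0)
  ok <- angle_diff_deg(ang, theta_deg) <= tol_deg
  kept <- rows[ok]
  if (any(!ok) && !is.null(pts)) {
    bad_ids <- unlist(lapply(rows[!ok], `[[`, "inlier_ids"))
    pool <- pts[pts$id %in% bad_ids, , drop = FALSE]
    refit <- detect_rows(pool, params)
    for (m in refit) {
      if (angle_diff_deg(rad2deg(atan(m$a)), theta_deg) <= tol_deg) {
        kept[[length(kept) + 1]] <- m
      }
    }
  }
  if (length(kept)) kept <- kept[order(vapply(kept, `[[`, 0, "b"))]
  structure(kept, class = "row_set")
}

#' Rotate detections so planting rows are horizontal
#'
#' Rotates all box centers by `-theta_deg` about the image center (pixel
#' frame, y down); box sizes are preserved (axis-aligned boxes are
#' re-centered, not sheared).  The applied rotation is recorded for the
#' quasi-mosaic stage.
#'
#' @param dets detection table of one image.
#' @param rec the image record.
#' @param theta_deg angle to remove, degrees (e.g. from
#'   [dominant_direction()]).
#' @return `list(detections, rotation)` where `rotation` is
#'   `list(theta_deg, center_px)`.
#' @export
rotate_to_horizontal <- function(dets, rec, theta_deg) {
  cx <- rec$width / 2; cy <- rec$height / 2
  phi <- deg2rad(-theta_deg)
  out <- dets
  if (nrow(dets)) {
    ctr <- det_centers(dets)
    dx <- ctr$x - cx; dy <- ctr$y - cy
    nx <- cx + cos(phi) * dx - sin(phi) * dy
    ny <- cy + sin(phi) * dx + cos(phi) * dy
    w <- dets$x_max - dets$x_min
    h <- dets$y_max - dets$y_min
    out$x_min <- nx - w / 2; out$x_max <- nx + w / 2
    out$y_min <- ny - h / 2; out$y_max <- ny + h / 2
  }
  list(detections = out,
       rotation = list(theta_deg = theta_deg, center_px = c(cx, cy)))
}

#' Assign detections to their nearest planting row
#'
#' Each detection center is assigned to the row line minimizing the
#' perpendicular distance (ties broken toward the lower row index, i.e.
#' the smaller intercept after sorting).  The scalar along-row position is
#' the arc-length of the center's projection onto the line, measured from
#' the row's x-span minimum.
#'
#' @param dets detection table (or point `data.frame`).
#' @param rows a non-empty `row_set`.
#' @return `data.frame(id, row, dist_px, along_px)`.
#' @export
assign_to_nearest_row <- function(dets, rows) {
  if (!length(rows)) stopf("no rows to assign to")
  pts <- if (!is.null(dets$x_min)) det_centers(dets) else dets
  if (is.null(pts$id)) pts$id <- seq_len(nrow(pts))
  D <- vapply(rows, function(m) perp_dist(pts, m$a, m$b),
              numeric(nrow(pts)))
  D <- matrix(D, nrow = nrow(pts))
  nearest <- max.col(-D, ties.method = "first")
  a_v <- vapply(rows, `[[`, 0, "a")[nearest]
  b_v <- vapply(rows, `[[`, 0, "b")[nearest]
  x0_v <- vapply(rows, function(m) m$x_span[1], 0)[nearest]
  foot_x <- (pts$x + a_v * (pts$y - b_v)) / (1 + a_v^2)
  along <- sqrt(1 + a_v^2) * (foot_x - x0_v)
  data.frame(id = pts$id, row = nearest,
             dist_px = D[cbind(seq_len(nrow(pts)), nearest)],
             along_px = along)
}

#' Field consensus direction
#'
#' Robust mode of the per-image dominant directions: each estimate is
#' scored by the total weight of all estimates within `tol_deg` of it
#' (axial distance, so 0 and 180 are equivalent), and the heaviest
#' cluster's weighted axial mean is returned.  Images that locked onto
#' the cross-row direction (a 90 degree error, typical for field-edge
#' images that see only a sliver of each row) or onto a spurious diagonal
#' simply end up outside the winning cluster.
#'
#' @param theta_deg per-image direction estimates (`NA` allowed).
#' @param weights non-negative weights (e.g. detections per image).
#' @param tol_deg cluster half-width in degrees.
#' @return consensus direction in degrees, `(-90, 90]`.
#' @export
consensus_direction <- function(theta_deg, weights = NULL, tol_deg = 10) {
  ok <- !is.na(theta_deg)
  if (!any(ok)) return(0)
  th <- theta_deg[ok]
  w <- (weights %||% rep(1, length(theta_deg)))[ok]
  support <- vapply(th, function(t0) {
    sum(w[angle_diff_deg(th, t0) <= tol_deg])
  }, 0)
  centre <- th[which.max(support)]
  sel <- angle_diff_deg(th, centre) <= tol_deg
  th2 <- deg2rad(2 * th[sel])
  norm_angle_deg(
    rad2deg(atan2(sum(w[sel] * sin(th2)), sum(w[sel] * cos(th2)))) / 2)
}

#' Per-image row detection over a detection set
#'
#' Convenience driver used by the pipeline: estimates the dominant
#' direction of every image, forms the field [consensus_direction()]
#' (weighted by detections per image), rotates each image horizontal --
#' by its own estimate when it agrees with the consensus within
#' `tol_deg`, by the consensus otherwise -- then detects rows on the
#' rotated centers and filters them by direction.
#'
#' @param dets detections across images.
#' @param meta image metadata.
#' @param params [ransac_params()].
#' @param tol_deg direction-filter tolerance.
#' @return named list (by image id) of
#'   `list(theta_deg, rotation, detections, rows)` where `detections`
#'   are the rotated (row-horizontal) boxes.
#' @export
detect_rows_images <- function(dets, meta, params = ransac_params(),
                               tol_deg = 10) {
  thetas <- rep(NA_real_, nrow(meta))
  per_dets <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    rec <- meta[i, , drop = FALSE]
    per_dets[[i]] <- dets[dets$image_id == rec$image_id, , drop = FALSE]
    thetas[i] <- tryCatch(
      dominant_direction(per_dets[[i]], rec, params),
      paniclepipe_insufficient_data = function(e) NA_real_)
  }
  theta_bar <- consensus_direction(
    thetas, vapply(per_dets, nrow, 0L))
  out <- list()
  for (i in seq_len(nrow(meta))) {
    rec <- meta[i, , drop = FALSE]
    theta <- if (!is.na(thetas[i]) &&
                 angle_diff_deg(thetas[i], theta_bar) <= tol_deg) {
      thetas[i]
    } else theta_bar
    rot <- rotate_to_horizontal(per_dets[[i]], rec, theta)
    pts <- det_centers(rot$detections)
    rows <- detect_rows(pts, params)
    rows <- filter_rows_by_direction(rows, 0, tol_deg, pts, params)
    out[[rec$image_id]] <- list(theta_deg = theta, rotation = rot$rotation,
                                detections = rot$detections, rows = rows)
  }
  out
}
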