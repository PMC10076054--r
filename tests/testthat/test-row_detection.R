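test_that("the line fit is exact on exact inputs and matches lm on noise", {
  expect_equal(fit_line(data.frame(x = c(0, 10), y = c(0, 10))),
               c(a = 1, b = 0))
  expect_equal(fit_line(data.frame(x = c(0, 10, 20), y = c(5, 5, 5))),
               c(a = 0, b = 5))
  set.seed(1)
  pts <- data.frame(x = runif(100, 0, 500))
  pts$y <- 0.02 * pts$x + 30 + rnorm(100)
  got <- fit_line(pts)
  ref <- stats::coef(stats::lm(y ~ x, pts))
  expect_equal(unname(got["a"]), unname(ref["x"]), tolerance = 1e-10)
  expect_equal(unname(got["b"]), unname(ref["(Intercept)"]),
               tolerance = 1e-10)
  ## truth recovered within 3 standard errors
  se <- summary(stats::lm(y ~ x, pts))$coefficients[, "Std. Error"]
  expect_lt(abs(got["a"] - 0.02), 3 * se["x"])
  expect_lt(abs(got["b"] - 30), 3 * se["(Intercept)"])

  expect_error(fit_line(data.frame(x = 1, y = 1)),
               class = "paniclepipe_degenerate_fit")
  expect_error(fit_line(data.frame(x = c(2, 2, 2), y = 1:3)),
               class = "paniclepipe_degenerate_fit")
})

test_that("single-row RANSAC recovers a noiseless line completely", {
  pts <- data.frame(x = seq(0, 490, by = 10), y = 0.1 * seq(0, 490, 10) + 7)
  m <- ransac_single(pts, ransac_params(t = 1, d = 10, seed = 1))
  expect_equal(m$n_inliers, 50)
  expect_equal(m$a, 0.1, tolerance = 1e-12)
  expect_equal(m$mean_residual, 0, tolerance = 1e-10)
})

test_that("single-row RANSAC picks one full row of a two-row scene,
           matching the exhaustive pair-line oracle", {
  pts <- make_row_points(2, spacing_px = 150, length_px = 600,
                         pts_per_row = 50, jitter_px = 0, seed = 2)
  m <- ransac_single(pts, ransac_params(t = 5, d = 10, seed = 3))
  rows_hit <- unique(pts$row[match(m$inlier_ids, pts$id)])
  expect_length(rows_hit, 1)
  expect_setequal(m$inlier_ids, pts$id[pts$row == rows_hit])

  oracle <- oracle_pair_lines(pts, t = 5, d = 10)
  expect_equal(oracle$err, 0, tolerance = 1e-9)
  expect_true(any(vapply(oracle$sets, setequal, TRUE, m$inlier_ids)))
})

test_that("RANSAC is deterministic under a fixed seed", {
  pts <- make_row_points(3, 150, 500, 30, jitter_px = 3, seed = 4)
  p <- ransac_params(t = 8, d = 10, seed = 99)
  expect_identical(ransac_single(pts, p), ransac_single(pts, p))
  expect_identical(detect_rows(pts, p), detect_rows(pts, p))
})

test_that("multi-row detection recovers every row exactly once", {
  expect_length(detect_rows(data.frame(x = numeric(), y = numeric())), 0)

  pts <- make_row_points(5, spacing_px = 300, length_px = 4000,
                         pts_per_row = 40, jitter_px = 2, seed = 5)
  rows <- detect_rows(pts, ransac_params(t = 8, d = 15, seed = 6))
  expect_length(rows, 5)
  for (m in rows) expect_lt(rad2deg_test(atan(m$a)), 0.5)
  ## ids of different rows never overlap, and >= 95% of points are
  ## assigned to their true row
  ids <- unlist(lapply(rows, `[[`, "inlier_ids"))
  expect_equal(anyDuplicated(ids), 0)
  asn <- assign_to_nearest_row(data.frame(x = pts$x, y = pts$y), rows)
  expect_gte(mean(asn$row == pts$row), 0.95)
})

test_that("collinear points form a single row under a small consensus", {
  pts <- data.frame(x = seq(0, 70, 10), y = seq(0, 70, 10))
  rows <- detect_rows(pts, ransac_params(n = 2, t = 1, d = 5, seed = 1))
  expect_length(rows, 1)
  expect_setequal(rows[[1]]$inlier_ids, 1:8)
})

test_that("row count responds monotonically to the consensus and threshold", {
  pts <- make_row_points(4, 150, 800, 25, jitter_px = 3, seed = 7)
  n_by_d <- vapply(c(5, 10, 20, 24), function(d) {
    length(detect_rows(pts, ransac_params(t = 8, d = d, seed = 1)))
  }, 0)
  expect_true(all(diff(n_by_d) <= 0))
  n_by_t <- vapply(c(1, 8, 30), function(t) {
    length(detect_rows(pts, ransac_params(t = t, d = 10, seed = 1)))
  }, 0)
  expect_true(all(diff(n_by_t) >= 0))
})

test_that("the dominant direction tracks the true row angle", {
  flat <- make_row_points(1, 150, 900, 60, jitter_px = 0, seed = 8)
  rec <- image_records("a", 900, 900, 0.5)
  expect_equal(dominant_direction(flat, rec, ransac_params(t = 5, d = 10,
                                                           seed = 1)), 0,
               tolerance = 1e-8)

  tilted <- make_row_points(4, 150, 900, 60, jitter_px = 2,
                            slope = tan(7 * pi / 180), seed = 9)
  th <- dominant_direction(tilted, rec, ransac_params(t = 20, d = 15,
                                                      seed = 2))
  expect_lt(abs(th - 7), 0.5)

  blob <- data.frame(x = rnorm(12, 450, 5), y = rnorm(12, 450, 300))
  expect_error(dominant_direction(blob, rec,
                                  ransac_params(t = 0.5, d = 10, seed = 3)),
               class = "paniclepipe_insufficient_data")
})

test_that("near-vertical rows are measured via the axis swap", {
  vert <- make_row_points(3, 150, 900, 60, jitter_px = 2, seed = 10)
  swapped <- data.frame(x = vert$y, y = vert$x, id = vert$id)
  rec <- image_records("a", 900, 1400, 0.5)
  th <- dominant_direction(swapped, rec, ransac_params(t = 20, d = 15,
                                                       seed = 4))
  expect_lt(angle_diff_test(th, 90), 0.5)
})

test_that("direction filtering removes cross-row artefacts and refits", {
  pts <- make_row_points(4, 150, 1000, 30, jitter_px = 2, seed = 11)
  params <- ransac_params(t = 8, d = 10, seed = 5)
  rows <- detect_rows(pts, params)
  expect_identical(filter_rows_by_direction(rows, 0, tol_deg = 90),
                   structure(rows[order(vapply(rows, `[[`, 0, "b"))],
                             class = "row_set"))
  kept <- filter_rows_by_direction(rows, 0, tol_deg = 10, pts, params)
  ang <- vapply(kept, function(m) atan(m$a) * 180 / pi, 0)
  expect_true(all(abs(ang) <= 10))

  ## inject a diagonal line of false positives crossing all rows
  diag <- data.frame(x = seq(100, 900, length.out = 15),
                     y = seq(100, 550, length.out = 15),
                     row = 0, id = nrow(pts) + 1:15)
  both <- rbind(pts, diag)
  rows2 <- detect_rows(both, params)
  kept2 <- filter_rows_by_direction(rows2, 0, tol_deg = 10, both, params)
  ang2 <- vapply(kept2, function(m) atan(m$a) * 180 / pi, 0)
  expect_true(all(abs(ang2) <= 10))
})

test_that("horizontal correction is a pure rotation about the centre", {
  rec <- image_records("a", 800, 800, 0.5)
  dets <- detections("a", x_min = 500 - 10, y_min = 390,
                     x_max = 500 + 10, y_max = 410)  # centre (500, 400)
  same <- rotate_to_horizontal(dets, rec, 0)
  expect_equal(same$detections, dets)

  out <- rotate_to_horizontal(dets, rec, 90)
  ctr <- det_centers(out$detections)
  expect_equal(c(ctr$x, ctr$y), c(400, 300), tolerance = 1e-9)

  ## rotation-matrix oracle on random points and angles
  set.seed(12)
  for (theta in c(-63, -7, 13.5, 88)) {
    d <- detections("a", runif(20, 0, 780), runif(20, 0, 780),
                    781:800, 781:800)
    got <- det_centers(rotate_to_horizontal(d, rec, theta)$detections)
    phi <- -theta * pi / 180
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    ref <- t(R %*% t(as.matrix(det_centers(d)[, c("x", "y")]) -
                       matrix(400, 20, 2, byrow = TRUE))) + 400
    expect_equal(as.matrix(got[, c("x", "y")]), ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  ## rotating a tilted field then refitting leaves the rows horizontal
  tilted <- make_row_points(3, 200, 700, 40, jitter_px = 1,
                            slope = tan(12 * pi / 180), seed = 13)
  d <- detections("a", tilted$x - 5, tilted$y - 5, tilted$x + 5,
                  tilted$y + 5)
  rot <- rotate_to_horizontal(d, rec, 12)
  rows <- detect_rows(det_centers(rot$detections),
                      ransac_params(t = 8, d = 15, seed = 6))
  for (m in rows) expect_lt(abs(m$a), tan(0.5 * pi / 180))
})

test_that("nearest-row assignment projects onto the line and breaks ties low", {
  rows <- detect_rows(data.frame(x = rep(c(0, 100, 200, 300, 400), 2),
                                 y = rep(c(0, 150), each = 5)),
                      ransac_params(t = 1, d = 2, seed = 1))
  expect_length(rows, 2)
  asn <- assign_to_nearest_row(data.frame(x = c(50, 50, 50),
                                          y = c(0, 75, 140)), rows)
  expect_equal(asn$row, c(1, 1, 2))  # on-line, midpoint tie -> lower, near
  expect_equal(asn$dist_px[1], 0)
  expect_equal(asn$along_px, c(50, 50, 50))
  expect_error(assign_to_nearest_row(data.frame(x = 1, y = 1),
                                     structure(list(), class = "row_set")))
})
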