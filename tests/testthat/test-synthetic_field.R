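test_that("field generation is deterministic and isolates the seed", {
  cfg <- field_config(n_rows = 4, row_length_m = 8, heads_per_m = 5,
                      seed = 42)
  t1 <- generate_field(cfg)
  t2 <- generate_field(cfg)
  expect_identical(t1, t2)

  cfg2 <- cfg; cfg2$seed <- 43L
  t3 <- generate_field(cfg2)
  expect_identical(t1$rows, t3$rows)          # row lines do not depend on seed
  expect_false(isTRUE(all.equal(t1$heads$along_m, t3$heads$along_m)))
})

test_that("zero intensity yields an empty head set but intact rows", {
  truth <- generate_field(field_config(n_rows = 3, heads_per_m = 0))
  expect_equal(nrow(truth$heads), 0)
  expect_equal(nrow(truth$rows), 3)
})

test_that("gaps are carved out and counts follow the Poisson law", {
  gaps <- data.frame(row = 1, start_m = 2, end_m = 4)
  counts <- vapply(seq_len(400), function(s) {
    truth <- generate_field(field_config(n_rows = 1, row_length_m = 10,
                                         heads_per_m = 5, gaps = gaps,
                                         cross_jitter_sd_m = 0, seed = s))
    expect_true(all(truth$heads$along_m <= 2 | truth$heads$along_m >= 4))
    nrow(truth$heads)
  }, 0)
  ## independent re-simulation of the same thinned process: Poisson with
  ## intensity 5/m over the remaining 8 m of row
  set.seed(990)
  ref <- rpois(400, 5 * 8)
  expect_lt(abs(mean(counts) - mean(ref)), 3 * sqrt(2 * 40 / 400))
})

test_that("per-row truth counts sum to the total head count", {
  truth <- generate_field(field_config(n_rows = 7, heads_per_m = 4,
                                       seed = 11))
  expect_equal(sum(truth_row_counts(truth)$count), nrow(truth$heads))
})

test_that("a head under the camera maps to a centred box of the exact size", {
  cfg <- field_config(n_rows = 1, row_length_m = 2, heads_per_m = 0,
                      head_diameter_cm = 10)
  truth <- generate_field(cfg)
  truth$heads <- data.frame(head_id = 1L, row = 1L, along_m = 1,
                            cross_m = 0, x_m = 1, y_m = 0)
  cap <- single_camera_cap(truth, e = 1, n = 0, gsd = 0.25)
  got <- capture_images(truth, cap)
  expect_equal(nrow(got$detections), 1)
  ctr <- det_centers(got$detections)
  expect_equal(ctr$x, 400)  # W/2
  expect_equal(ctr$y, 400)  # H/2
  expect_equal(got$detections$x_max - got$detections$x_min, 40)  # 10 cm / 0.25
})

test_that("ground-truth boxes equal the brute-force point-in-footprint count", {
  truth <- generate_field(field_config(n_rows = 4, row_length_m = 6,
                                       heads_per_m = 5, seed = 3))
  cap <- capture_config(gsd_cm_px = 0.5, image_w_px = 800, image_h_px = 800,
                        overlap_fraction = 0.5, margin_m = 1)
  got <- capture_images(truth, cap)
  pos <- latlon_to_local(got$meta$lat, got$meta$lon,
                         truth$config$origin_lat, truth$config$origin_lon)
  half <- 800 * 0.5 / 200
  expected <- 0L
  for (i in seq_len(nrow(pos))) {
    for (h in seq_len(nrow(truth$heads))) {
      dx <- truth$heads$x_m[h] - pos$e[i]
      dy <- truth$heads$y_m[h] - pos$n[i]
      if (dx >= -half && dx < half && dy > -half && dy <= half) {
        expected <- expected + 1L
      }
    }
  }
  expect_equal(nrow(got$detections), expected)
  expect_gte(nrow(got$detections), nrow(truth$heads))
})

test_that("capture then inverse transform recovers field coordinates", {
  truth <- generate_field(field_config(n_rows = 3, row_length_m = 5,
                                       heads_per_m = 4, seed = 8))
  cap <- capture_config(gsd_cm_px = 0.5, image_w_px = 1000,
                        image_h_px = 1000, overlap_fraction = 0.4,
                        margin_m = 1)
  got <- capture_images(truth, cap)
  pos <- latlon_to_local(got$meta$lat, got$meta$lon,
                         truth$config$origin_lat, truth$config$origin_lon)
  ctr <- det_centers(got$detections)
  i <- match(got$detections$image_id, got$meta$image_id)
  s <- 0.5 / 100
  e_back <- pos$e[i] + (ctr$x - 500) * s
  n_back <- pos$n[i] - (ctr$y - 500) * s
  h <- match(got$detections$head_id, truth$heads$head_id)
  tol <- 0.5 / 200  # gsd / 2 in metres
  expect_lt(max(abs(e_back - truth$heads$x_m[h])), tol)
  expect_lt(max(abs(n_back - truth$heads$y_m[h])), tol)
})

test_that("detector noise honours its identity, wipe-out and binomial limits", {
  truth <- generate_field(field_config(n_rows = 5, row_length_m = 10,
                                       heads_per_m = 5, seed = 2))
  cap <- capture_config(gsd_cm_px = 0.5, image_w_px = 2400,
                        image_h_px = 2400, overlap_fraction = 0,
                        margin_m = 1)
  got <- capture_images(truth, cap)

  clean <- corrupt_detections(got$detections,
                              detector_noise(conf_true = NULL, seed = 5),
                              got$meta)
  expect_equal(clean, got$detections)

  gone <- corrupt_detections(got$detections,
                             detector_noise(fn_prob = 1, seed = 5),
                             got$meta)
  expect_equal(nrow(gone), 0)

  n0 <- nrow(got$detections)
  kept <- vapply(seq_len(200), function(s) {
    nrow(corrupt_detections(got$detections,
                            detector_noise(fn_prob = 0.2, seed = s),
                            got$meta))
  }, 0)
  expect_lt(abs(mean(kept) - 0.8 * n0), 3 * sqrt(n0 * 0.2 * 0.8 / 200))
})

test_that("rendered rasters show one blob per well-separated head", {
  cfg <- field_config(n_rows = 2, row_spacing_m = 0.75, row_length_m = 2,
                      heads_per_m = 0, head_diameter_cm = 10)
  truth <- generate_field(cfg)
  truth$heads <- data.frame(head_id = 1:4, row = c(1, 1, 2, 2),
                            along_m = c(0.5, 1.5, 0.5, 1.5),
                            cross_m = c(0, 0, 0.75, 0.75),
                            x_m = c(0.5, 1.5, 0.5, 1.5),
                            y_m = c(0, 0, 0.75, 0.75))
  cap <- single_camera_cap(truth, e = 1, n = 0.375, gsd = 1, w = 300,
                           h = 200)
  rec <- capture_images(truth, cap)$meta[1, ]
  img <- render_image(rec, truth)
  expect_equal(count_components(img > 0.5), 4)
  expect_identical(img, render_image(rec, truth))
  empty <- truth; empty$heads <- truth$heads[0, ]
  expect_true(all(render_image(rec, empty) == 0.15))
})
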