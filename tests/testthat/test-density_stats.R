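test_that("row and image densities follow their defining ratios", {
  expect_equal(row_density(10, 400, 0.25), 10)   # heads per metre
  expect_equal(row_density(0, 400, 0.25), 0)
  expect_equal(image_density(5, 400, 400, 0.25), 5)  # heads per m^2
  expect_equal(image_density(0, 400, 400, 0.25), 0)
  expect_error(row_density(1, 0, 0.25), "positive")
  expect_error(image_density(1, 400, 400, -1), "positive")
})

test_that("densities of simulated rows match the Poisson intensity", {
  d_r <- vapply(seq_len(200), function(s) {
    truth <- generate_field(field_config(n_rows = 1, row_length_m = 10,
                                         heads_per_m = 4, seed = s))
    ## a 10 m row imaged edge-to-edge at 0.5 cm/px
    row_density(nrow(truth$heads), 2000, 0.5)
  }, 0)
  expect_lt(abs(mean(d_r) - 4), 3 * sqrt(4 / 10 / 200))

  d_i <- vapply(seq_len(200), function(s) {
    truth <- generate_field(field_config(n_rows = 4, row_spacing_m = 0.5,
                                         row_length_m = 2, heads_per_m = 3,
                                         seed = s + 300))
    ## 4 rows at 0.5 m spacing on a 2 x 2 m footprint: 6 heads/m^2
    image_density(nrow(truth$heads), 400, 400, 0.5)
  }, 0)
  expect_lt(abs(mean(d_i) - 6), 3 * sqrt(6 / 4 / 200))
})

test_that("gap detection scans spans, edges and empty rows", {
  g <- detect_gaps(c(0, 10, 20, 80), c(0, 80))
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start_cm, g$end_cm, g$length_cm), c(20, 80, 60))

  expect_equal(nrow(detect_gaps(seq(0, 200, by = 25), c(0, 200))), 0)

  empty <- detect_gaps(numeric(), c(0, 120))
  expect_equal(empty$length_cm, 120)
  expect_equal(nrow(detect_gaps(numeric(), c(0, 40))), 0)
})

test_that("planted gaps are recovered from simulated rows", {
  gaps <- data.frame(row = c(2, 4), start_m = c(3, 6), end_m = c(5, 8))
  hit <- 0L
  for (s in 1:20) {
    truth <- generate_field(field_config(n_rows = 5, row_length_m = 10,
                                         heads_per_m = 7, gaps = gaps,
                                         seed = s))
    found <- lapply(1:5, function(r) {
      detect_gaps(truth$heads$along_m[truth$heads$row == r] * 100,
                  c(0, 1000))
    })
    ok <- vapply(seq_len(nrow(gaps)), function(k) {
      f <- found[[gaps$row[k]]]
      any(f$start_cm < gaps$start_m[k] * 100 + 50 &
            f$end_cm > gaps$end_m[k] * 100 - 50)
    }, TRUE)
    hit <- hit + sum(ok)
  }
  expect_equal(hit, 40L)  # every planted 2 m gap, every seed
})

test_that("row profiles are flat for a comb and conserve the head count", {
  comb <- seq(5, 995, by = 10)  # uniform 10 cm spacing -> 10 heads/m
  prof <- row_profile(comb, c(0, 1000))
  interior <- prof$density[prof$pos_cm >= 150 & prof$pos_cm <= 850]
  expect_equal(interior, rep(10, length(interior)), tolerance = 0.02)

  none <- row_profile(numeric(), c(0, 300))
  expect_true(all(none$density == 0))

  set.seed(31)
  pos <- sort(runif(60, 0, 1000))
  prof2 <- row_profile(pos, c(0, 1000))
  ## integral of heads/m over metres of row ~ total count
  expect_equal(sum(prof2$raw_density) / 100, 60, tolerance = 0.06)
})

test_that("the smoothing kernel is normalized and conservative", {
  g <- gaussian_kernel_1d(100 / 6, 101)
  expect_lt(abs(sum(g) - 1), 1e-9)
  k2 <- outer(g, g)
  expect_lt(abs(sum(k2) - 1), 1e-9)
})

test_that("the density map matches the brute-force window and smoother", {
  set.seed(32)
  n <- 70
  fd <- data.frame(east_m = runif(n, 0, 1.4), north_m = runif(n, 0, 1.2))
  map <- field_density_map(fd, extent = c(0, 1.4, 0, 1.2), window_px = 40,
                           sigma_px = 40 / 6, kernel_size = 41)
  ## pre-smoothing: exact integer counts per window
  expect_true(all(map$moving_sum == round(map$moving_sum)))
  ref_raw <- oracle_moving_density(map$counts, 40, (40 * 0.01)^2)
  expect_lt(max(abs(map$raw_density - ref_raw)), 1e-9)
  ref_sm <- oracle_gaussian_smooth(ref_raw, outer(gaussian_kernel_1d(40 / 6, 41),
                                                  gaussian_kernel_1d(40 / 6, 41)))
  expect_lt(max(abs(map$density - ref_sm)), 1e-9)
})

test_that("a single head and an empty field produce the expected maps", {
  one <- field_density_map(data.frame(east_m = 1.5, north_m = 1.5),
                           extent = c(0, 3, 0, 3), smooth = FALSE)
  ## every window that covers the head counts exactly 1 head/m^2
  expect_equal(sort(unique(as.vector(one$moving_sum))), c(0, 1))
  expect_equal(max(one$raw_density), 1)

  zero <- field_density_map(data.frame(east_m = numeric(),
                                       north_m = numeric()),
                            extent = c(0, 2, 0, 2))
  expect_true(all(zero$density == 0))
})

test_that("map values are invariant to translation and record order", {
  set.seed(33)
  fd <- data.frame(east_m = runif(50, 0, 2), north_m = runif(50, 0, 2))
  m1 <- field_density_map(fd, extent = c(0, 2, 0, 2), window_px = 50,
                          kernel_size = 31, sigma_px = 8)
  shifted <- data.frame(east_m = fd$east_m + 10, north_m = fd$north_m - 5)
  m2 <- field_density_map(shifted, extent = c(10, 12, -5, -3),
                          window_px = 50, kernel_size = 31, sigma_px = 8)
  expect_equal(m1$density, m2$density)
  m3 <- field_density_map(fd[sample(50), ], extent = c(0, 2, 0, 2),
                          window_px = 50, kernel_size = 31, sigma_px = 8)
  expect_equal(m1$density, m3$density)
})

test_that("smoothing leaves the interior mean essentially unchanged", {
  ## a homogeneous field large enough that boundary strips are a small
  ## fraction of the interior: smoothing must not move mass
  set.seed(34)
  n <- rpois(1, 6 * 16 * 12)
  fd <- data.frame(east_m = runif(n, 0, 16), north_m = runif(n, 0, 12))
  map <- field_density_map(fd, extent = c(0, 16, 0, 12))
  H <- nrow(map$density); W <- ncol(map$density)
  ri <- 101:(H - 100); ci <- 101:(W - 100)
  expect_lt(abs(mean(map$density[ri, ci]) / mean(map$raw_density[ri, ci]) - 1),
            0.001)
})

test_that("per-image statistics tie rows, counts and gaps together", {
  pts <- make_row_points(3, 200, 760, 30, jitter_px = 1, seed = 35,
                         y0 = 200)
  dets <- detections("a", pts$x - 4, pts$y - 4, pts$x + 4, pts$y + 4)
  rec <- image_records("a", 800, 800, 0.5)
  rows <- detect_rows(det_centers(dets), ransac_params(t = 10, d = 10,
                                                       seed = 1))
  st <- image_stats(dets, rec, rows)
  expect_equal(st$c_i, 90)
  expect_equal(st$d_i, image_density(90, 800, 800, 0.5))
  expect_equal(sum(st$per_row$c_r), 90)  # every detection lands on a row
  expect_equal(st$d_i, sum(st$per_row$d_r * st$per_row$length_m) /
                 (800 * 800 * 0.25 / 1e4), tolerance = 0.2)
})
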