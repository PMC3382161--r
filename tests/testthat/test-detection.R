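test_that("roundness coefficient matches analytic values", {
  # circle
  expect_equal(compute_irc(pi * 1^2, 2 * pi * 1), 1)
  expect_equal(compute_irc(pi * 17^2, 2 * pi * 17), 1)
  # square
  expect_equal(compute_irc(4, 8), pi / 4, tolerance = 1e-12)
  # thin 2 x 100 rectangle
  expect_equal(compute_irc(200, 204), 4 * pi * 200 / 204^2, tolerance = 1e-12)
  expect_error(compute_irc(0, 5), "positive")
  expect_error(compute_irc(5, -1), "positive")
})

test_that("analytic IRC decreases monotonically with rectangle elongation", {
  k <- 2
  irc_rect <- function(L) compute_irc(k * L, 2 * (k + L))
  Ls <- c(2, 5, 10, 25, 60, 150)
  vals <- vapply(Ls, irc_rect, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("rasterized disks of radius >= 15 px have IRC in [0.95, 1]", {
  for (r in c(15, 20, 30)) {
    f <- disk_frame(2 * r + 11, 2 * r + 11, r + 5.3, r + 5.7, r)
    per <- crofton_perimeter(f > 0)
    irc <- compute_irc(sum(f > 0), per)
    expect_gte(irc, 0.95)
    expect_lte(irc, 1)
  }
})

test_that("IRC is scale-invariant within discretization tolerance", {
  irc_of_disk <- function(r) {
    f <- disk_frame(2 * r + 11, 2 * r + 11, r + 5.5, r + 5.5, r)
    compute_irc(sum(f > 0), crofton_perimeter(f > 0))
  }
  vals_d <- vapply(c(15, 25, 40), irc_of_disk, numeric(1))
  expect_lt(max(vals_d) - min(vals_d), 0.03)

  irc_of_square <- function(a) {
    f <- matrix(0, a + 10, a + 10)
    f[6:(5 + a), 6:(5 + a)] <- 1
    compute_irc(sum(f), crofton_perimeter(f))
  }
  vals_s <- vapply(c(15, 30, 60), irc_of_square, numeric(1))
  expect_lt(max(vals_s) - min(vals_s), 0.03)
})

test_that("crofton perimeter approximates the analytic disk circumference", {
  for (r in c(10, 20, 35)) {
    f <- disk_frame(2 * r + 11, 2 * r + 11, r + 5.5, r + 5.5, r)
    expect_lt(abs(crofton_perimeter(f > 0) - 2 * pi * r) / (2 * pi * r), 0.05)
  }
})

test_that("segmentation: blank frame, single disk, two disks", {
  params <- segmentation_params()
  px <- 280 / 512
  expect_equal(nrow(segment_cells(matrix(0, 64, 64), params, px)), 0)

  r <- 10
  f <- disk_frame(64, 64, 30.5, 25.5, r)
  det <- segment_cells(f, params, px)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$pixel_count - pi * r^2) / (pi * r^2), 0.05)
  expect_gt(det$irc, 0.9)

  f2 <- disk_frame(128, 128, 30, 30, 10)
  f2[roundtrack:::rasterize_disk(95, 90, 10, 128, 128)] <- 1
  det2 <- segment_cells(f2, segmentation_params(smoothing_sigma_px = 0,
                                                threshold_method = "fixed",
                                                fixed_threshold = 0.5), px)
  expect_equal(nrow(det2), 2)
  expect_equal(sort(det2$x_um / px), c(30, 95), tolerance = 0.5 / 30)
  expect_equal(sort(det2$y_um / px), c(30, 90), tolerance = 0.5 / 30)
})

test_that("border-touching and out-of-range components are discarded", {
  px <- 1
  f <- matrix(0, 64, 64)
  f[1:10, 20:30] <- 1                        # touches the border
  f[30:31, 40:41] <- 1                       # 4 px: below min area
  f[roundtrack:::rasterize_disk(45, 15, 6, 64, 64)] <- 1   # valid
  det <- segment_cells(f, segmentation_params(smoothing_sigma_px = 0,
                                              threshold_method = "fixed",
                                              fixed_threshold = 0.5,
                                              min_area_um2 = 10,
                                              max_area_um2 = 500),
                       pixel_size_um = px)
  expect_equal(nrow(det), 1)
  expect_equal(det$x_um, 45, tolerance = 0.5)
})

test_that("holes are filled before measurement when requested", {
  px <- 1
  f <- matrix(0, 40, 40)
  f[roundtrack:::rasterize_disk(20, 20, 10, 40, 40)] <- 1
  f[19:21, 19:21] <- 0
  p_fill <- segmentation_params(smoothing_sigma_px = 0,
                                threshold_method = "fixed",
                                fixed_threshold = 0.5, min_area_um2 = 10,
                                max_area_um2 = 500)
  det <- segment_cells(f, p_fill, px)
  expect_equal(det$pixel_count, sum(f) + 9)
})

test_that("components are 8-connected", {
  px <- 1
  f <- matrix(0, 32, 32)
  # two 3x3 blocks touching only at a corner: one component under
  # 8-connectivity, two under 4-connectivity; total area 18 px
  f[10:12, 10:12] <- 1
  f[13:15, 13:15] <- 1
  det <- segment_cells(f, segmentation_params(smoothing_sigma_px = 0,
                                              threshold_method = "fixed",
                                              fixed_threshold = 0.5,
                                              min_area_um2 = 1,
                                              max_area_um2 = 500,
                                              fill_holes = FALSE), px)
  expect_equal(nrow(det), 1)
  expect_equal(det$pixel_count, 18)
})

test_that("segmentation recall on noiseless simulator output is perfect", {
  cfg <- small_config(seed = 13, noise_sd = 0, drift = matrix(0, 8, 2),
                      field_size_px = c(192, 192), min_separation_um = 25,
                      round_speed_um_min = 1, dendritic_speed_um_min = 0.5)
  sim <- simulate_cell_channel(cfg)
  n_cells <- cfg$n_round_cells + cfg$n_dendritic_cells
  for (t in c(1, 4, 8)) {
    det <- segment_cells(sim$frames[[t]], segmentation_params(),
                         cfg$pixel_size_um, frame_index = t - 1L)
    expect_equal(nrow(det), n_cells)
  }
})
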