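test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_config(seed = 7)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$movie$structural, b$movie$structural)
  expect_identical(a$movie$cell, b$movie$cell)
  expect_identical(a$truth, b$truth)

  tt1 <- simulate_track_table(cfg)
  tt2 <- simulate_track_table(cfg)
  expect_identical(tt1, tt2)
})

test_that("structural channel: zero drift gives identical frames, constant drift translates", {
  cfg0 <- small_config(seed = 3, noise_sd = 0,
                       drift = matrix(0, 8, 2))
  shg <- simulate_structural_channel(cfg0)
  for (t in 2:length(shg)) expect_identical(shg[[t]], shg[[1]])

  dr <- cbind(0:7, 0)   # cumulative drift (t, 0) px at frame t
  cfgd <- small_config(seed = 3, noise_sd = 0, drift = dr)
  shgd <- simulate_structural_channel(cfgd)
  for (t in c(3, 8)) {
    dy <- dr[t, 1]
    # frame t equals frame 0 with content moved down by dy rows
    expect_equal(shgd[[t]][(dy + 1):128, ], shgd[[1]][1:(128 - dy), ])
  }
})

test_that("excessive drift errors out", {
  cfg <- small_config(drift = rbind(c(0, 0), matrix(c(200, 0), 7, 2,
                                                    byrow = TRUE)))
  expect_error(simulate_structural_channel(cfg), "out of frame")
})

test_that("cell channel bookkeeping: labels, track lengths, degenerate motion", {
  cfg <- small_config(seed = 5, n_round_cells = 5, n_dendritic_cells = 5,
                      min_separation_um = 12)
  sim <- simulate_cell_channel(cfg)
  expect_equal(nrow(sim$labels), 10)
  expect_equal(sort(table(sim$truth$cell_id), decreasing = TRUE),
               sort(rep(8L, 10), decreasing = TRUE), ignore_attr = TRUE)
  expect_equal(nrow(sim$drift), cfg$n_frames)

  cfg0 <- small_config(seed = 5, round_speed_um_min = 0,
                       dendritic_speed_um_min = 0,
                       drift = matrix(0, 8, 2))
  sim0 <- simulate_cell_channel(cfg0)
  for (cid in unique(sim0$truth$cell_id)) {
    tr <- sim0$truth[sim0$truth$cell_id == cid, ]
    expect_equal(var(tr$x_um), 0)
    expect_equal(var(tr$y_um), 0)
  }
})

test_that("impossible placement density raises an error", {
  cfg <- small_config(n_round_cells = 50, n_dendritic_cells = 50,
                      min_separation_um = 40)
  expect_error(simulate_cell_channel(cfg), "minimum separation")
})

test_that("rendered centroid equals true position plus drift within 0.5 px (noiseless)", {
  cfg <- small_config(seed = 9, n_round_cells = 1, n_dendritic_cells = 0,
                      noise_sd = 0, drift_sd_px = 2)
  sim <- simulate_cell_channel(cfg)
  px <- cfg$pixel_size_um
  for (t in seq_along(sim$frames)) {
    det <- segment_cells(sim$frames[[t]],
                         segmentation_params(smoothing_sigma_px = 0,
                                             threshold_method = "fixed",
                                             fixed_threshold = 0.5),
                         pixel_size_um = px, frame_index = t - 1L)
    expect_equal(nrow(det), 1)
    tru <- sim$truth[sim$truth$frame == t - 1L, ]
    expect_lt(abs(det$x_um / px - (tru$x_um / px + sim$drift$dx_px[t])), 0.5)
    expect_lt(abs(det$y_um / px - (tru$y_um / px + sim$drift$dy_px[t])), 0.5)
  }
})

test_that("track table: MRC concentrates near class means and classes separate", {
  cfg <- small_config(seed = 11, n_frames = 60, n_round_cells = 40,
                      n_dendritic_cells = 40)
  tt <- simulate_track_table(cfg, irc_means = c(0.25, 0.55), irc_sd = 0.05)
  expect_true(all(tt$tracks$irc >= 0 & tt$tracks$irc <= 1))
  mrc <- tapply(tt$tracks$irc, tt$tracks$cell_id, mean)
  lab <- tt$labels$label[match(names(mrc), tt$labels$cell_id)]
  # law of large numbers: per-cell means near the class mean
  expect_lt(max(abs(mrc[lab == "dendritic"] - 0.25)), 0.05)
  expect_lt(max(abs(mrc[lab == "round"] - 0.55)), 0.05)
  # < 5% of per-frame IRC mass beyond the class midpoint
  mid <- 0.4
  irc_d <- tt$tracks$irc[tt$tracks$cell_id %in%
                           tt$labels$cell_id[lab == "dendritic"]]
  irc_r <- tt$tracks$irc[tt$tracks$cell_id %in%
                           tt$labels$cell_id[lab == "round"]]
  expect_lt(mean(irc_d > mid), 0.05)
  expect_lt(mean(irc_r < mid), 0.05)
})

test_that("single-class track table and sd-zero validation", {
  cfg <- small_config(n_round_cells = 4, n_dendritic_cells = 0)
  tt <- simulate_track_table(cfg, irc_sd = 0)
  expect_true(all(tt$labels$label == "round"))
  expect_true(all(tt$tracks$irc == 0.55))
  expect_error(simulate_track_table(cfg, irc_means = c(0.25, 1.2)),
               "irc means|means")
})

test_that("movie TIFF and config round-trip through disk", {
  cfg <- small_config(seed = 2, n_frames = 3)
  sim <- simulate_movie(cfg)
  base <- file.path(tempdir(), "rt_roundtrip")
  write_movie_tiff(sim$movie, base)
  rd <- read_movie_tiff(paste0(base, "_cell.tif"), paste0(base, "_shg.tif"),
                        pixel_size_um = cfg$pixel_size_um,
                        frame_interval_min = cfg$frame_interval_min)
  expect_equal(n_frames(rd), 3)
  # writer clips to [0,1] and quantizes; structure must survive
  expect_gt(cor(as.vector(rd$structural[[2]]),
                as.vector(pmin(pmax(sim$movie$structural[[2]], 0), 1))), 0.99)

  pcfg <- file.path(tempdir(), "rt_cfg.txt")
  write_sim_config(cfg, pcfg)
  cfg2 <- read_sim_config(pcfg)
  expect_equal(cfg2$n_frames, cfg$n_frames)
  expect_equal(cfg2$round_speed_um_min, cfg$round_speed_um_min)
  expect_identical(simulate_structural_channel(cfg2)[[2]],
                   simulate_structural_channel(cfg)[[2]])
})
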