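make_det <- function(frame, x, y, irc = rep(0.5, length(frame)))
  data.frame(frame = frame, x_um = x, y_um = y, irc = irc)

test_that("two stationary well-separated cells give two full tracks", {
  det <- rbind(make_det(rep(0:4, each = 1), rep(10, 5), rep(10, 5)),
               make_det(rep(0:4, each = 1), rep(60, 5), rep(60, 5)))
  tr <- link_detections(det, linking_params(max_displacement_um = 20,
                                            memory_frames = 0,
                                            min_track_length = 3))
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 5))
})

test_that("near-swap configurations match the exhaustive assignment", {
  # two cells approaching within linking range: optimal assignment must be
  # the minimum-total-squared-displacement one
  det <- rbind(make_det(0, c(10, 18), c(10, 10)),
               make_det(1, c(13, 16), c(10, 10)),
               make_det(2, c(15, 21), c(10, 10)))
  tr <- link_detections(det, linking_params(max_displacement_um = 10,
                                            memory_frames = 0,
                                            min_track_length = 2))
  got <- track_set_signature(linked_to_track_list(tr))
  want <- track_set_signature(oracle_link(det, 10, min_len = 2))
  expect_identical(got, want)
})

test_that("memory bridges a single missing detection; memory 0 splits", {
  det <- make_det(c(0, 1, 3, 4), c(10, 11, 13, 14), rep(10, 4))
  tr1 <- link_detections(det, linking_params(max_displacement_um = 10,
                                             memory_frames = 1,
                                             min_track_length = 3))
  expect_equal(length(unique(tr1$track_id)), 1)
  expect_equal(sum(tr1$track_id == 1), 4)   # observed frames only

  tr0 <- link_detections(det, linking_params(max_displacement_um = 10,
                                             memory_frames = 0,
                                             min_track_length = 2))
  expect_equal(length(unique(tr0$track_id)), 2)
})

test_that("linking equals the exhaustive optimum on 20 seeded instances", {
  for (seed in 1:20) {
    det <- random_link_instance(seed)
    tr <- link_detections(det, linking_params(max_displacement_um = 15,
                                              memory_frames = 0,
                                              min_track_length = 2))
    got <- track_set_signature(linked_to_track_list(tr))
    want <- track_set_signature(oracle_link(det, 15, min_len = 2))
    expect_identical(got, want)
  }
})

test_that("linking is invariant to within-frame detection order", {
  det <- random_link_instance(99)
  set.seed(1)
  shuf <- det[sample(nrow(det)), ]
  p <- linking_params(max_displacement_um = 15, memory_frames = 1,
                      min_track_length = 2)
  expect_identical(track_set_signature(linked_to_track_list(
    link_detections(det, p))),
    track_set_signature(linked_to_track_list(link_detections(shuf, p))))
})

test_that("simulator ground truth is recovered with zero identity switches", {
  cfg <- small_config(seed = 21, noise_sd = 0, drift = matrix(0, 8, 2),
                      field_size_px = c(192, 192),
                      min_separation_um = 30, n_round_cells = 2,
                      n_dendritic_cells = 2)
  sim <- simulate_cell_channel(cfg)
  det <- do.call(rbind, lapply(seq_along(sim$frames), function(t)
    segment_cells(sim$frames[[t]], segmentation_params(),
                  cfg$pixel_size_um, frame_index = t - 1L)))
  tr <- link_detections(det, linking_params())
  expect_equal(length(unique(tr$track_id)), 4)
  m <- match_tracks_to_truth(tr, sim$truth)
  expect_equal(sort(m$cell_id), 1:4)        # one track per true cell
  expect_true(all(m$mean_dist_um < 2))      # no identity switches
})

test_that("empty input yields empty output", {
  det <- make_det(integer(0), numeric(0), numeric(0))
  tr <- link_detections(det, linking_params())
  expect_equal(nrow(tr), 0)
  expect_true("track_id" %in% names(tr))
  expect_equal(nrow(track_summary(tr)), 0)
})

test_that("track summary arithmetic", {
  tracks <- data.frame(track_id = 1, frame = 0:15,
                       x_um = 0:15, y_um = 0, irc = 0.5)
  s <- track_summary(tracks, frame_interval_min = 2)
  expect_equal(s$n_frames_observed, 16)
  expect_equal(s$duration_min, 30)          # elapsed first-to-last
  expect_equal(s$observation_time_min, 32)  # per-frame convention

  gap <- data.frame(track_id = 1, frame = c(0, 1, 3), x_um = 1:3, y_um = 0,
                    irc = 0.5)
  sg <- track_summary(gap, 2)
  expect_equal(sg$n_frames_observed, 3)     # observed frames only
  expect_equal(sg$first_frame, 0)
  expect_equal(sg$last_frame, 3)
})
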