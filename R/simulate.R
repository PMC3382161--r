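#' Simulation configuration for synthetic two-channel lung movies
#'
#' Describes a synthetic imaging experiment that emulates the real regime:
#' a static collagen-like fiber mesh in the structural channel, drifting
#' rigidly over time, plus two motile cell populations in the cell channel —
#' fast round cells (monocyte-like disks) and slower dendritic-shaped cells
#' (star polygons with radiating arms). Defaults reproduce the acquisition
#' calibration of the imaging setup: a 512 px field spanning 280 um, one
#' z-projected frame every 2 minutes for one hour.
#'
#' Cells perform isotropic random walks (fixed step length
#' `speed * frame_interval`, uniform heading) and reflect at the field margins
#' so tracks are never censored. Drift is a cumulative integer random walk in
#' shift space, or any user-supplied per-frame cumulative shift matrix.
#'
#' @param field_size_px integer pair, image height and width in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param frame_interval_min minutes between frames.
#' @param n_frames number of frames (>= 2).
#' @param n_round_cells,n_dendritic_cells population sizes.
#' @param round_speed_um_min,dendritic_speed_um_min cell speeds in um/min.
#' @param round_radius_um radius of the round-cell disk.
#' @param dendritic_body_radius_um radius of the dendritic cell body.
#' @param dendritic_arm_count number of radiating arms (>= 3).
#' @param dendritic_arm_length_um arm length beyond the body radius.
#' @param drift optional `n_frames x 2` matrix of cumulative `(dy, dx)` pixel
#'   shifts (row 1 must be `(0, 0)`); if `NULL`, an integer random walk with
#'   per-frame step standard deviation `drift_sd_px` is generated from `seed`.
#' @param drift_sd_px per-frame drift step standard deviation in pixels.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param min_separation_um minimum initial centre-to-centre distance between
#'   cells; placement fails with an error if it cannot be honoured.
#' @param n_fibers number of collagen-like line segments in the structural
#'   texture.
#' @param seed integer RNG seed; identical seed and config give bit-identical
#'   output.
#' @return a list of class `rt_sim_config`.
#' @export
simulation_config <- function(field_size_px = c(512L, 512L),
                              pixel_size_um = 280 / 512,
                              frame_interval_min = 2,
                              n_frames = 31L,
                              n_round_cells = 10L,
                              n_dendritic_cells = 10L,
                              round_speed_um_min = 4,
                              dendritic_speed_um_min = 1.5,
                              round_radius_um = 5,
                              dendritic_body_radius_um = 3,
                              dendritic_arm_count = 5L,
                              dendritic_arm_length_um = 12,
                              drift = NULL,
                              drift_sd_px = 2,
                              noise_sd = 0.02,
                              min_separation_um = 25,
                              n_fibers = 60L,
                              seed = 1L) {
  stopifnot(length(field_size_px) == 2, all(field_size_px >= 16),
            pixel_size_um > 0, frame_interval_min > 0, n_frames >= 2,
            n_round_cells >= 0, n_dendritic_cells >= 0,
            round_speed_um_min >= 0, dendritic_speed_um_min >= 0,
            round_radius_um > 0, dendritic_body_radius_um > 0,
            dendritic_arm_count >= 3, dendritic_arm_length_um > 0,
            drift_sd_px >= 0, noise_sd >= 0, min_separation_um >= 0,
            n_fibers >= 1)
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    if (!identical(dim(drift), c(as.integer(n_frames), 2L)))
      stop("drift must be an n_frames x 2 matrix of cumulative shifts")
    if (any(drift[1, ] != 0)) stop("drift for frame 0 must be (0, 0)")
  }
  structure(list(field_size_px = as.integer(field_size_px),
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames),
                 n_round_cells = as.integer(n_round_cells),
                 n_dendritic_cells = as.integer(n_dendritic_cells),
                 round_speed_um_min = round_speed_um_min,
                 dendritic_speed_um_min = dendritic_speed_um_min,
                 round_radius_um = round_radius_um,
                 dendritic_body_radius_um = dendritic_body_radius_um,
                 dendritic_arm_count = as.integer(dendritic_arm_count),
                 dendritic_arm_length_um = dendritic_arm_length_um,
                 drift = drift, drift_sd_px = drift_sd_px,
                 noise_sd = noise_sd,
                 min_separation_um = min_separation_um,
                 n_fibers = as.integer(n_fibers),
                 seed = as.integer(seed)),
            class = "rt_sim_config")
}

# Evaluate expr under a local RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Cumulative drift trace of a simulation
#'
#' The drift shared by both simulated channels: either the matrix supplied in
#' the config or an integer random walk derived deterministically from the
#' config seed, so the structural and cell channel generators (and the ground
#' truth) always agree.
#'
#' @param config an [simulation_config()].
#' @return data.frame with columns `frame` (0-based), `dy_px`, `dx_px`
#'   (cumulative shift relative to frame 0).
#' @export
simulated_drift <- function(config) {
  stopifnot(inherits(config, "rt_sim_config"))
  if (!is.null(config$drift)) {
    cum <- config$drift
  } else {
    cum <- with_seed(config$seed + 1L, {
      steps <- matrix(round(stats::rnorm(2 * (config$n_frames - 1),
                                         sd = config$drift_sd_px)),
                      ncol = 2)
      rbind(c(0, 0), apply(steps, 2, cumsum))
    })
  }
  if (any(abs(cum[, 1]) >= config$field_size_px[1]) ||
      any(abs(cum[, 2]) >= config$field_size_px[2]))
    stop("drift pushes the texture fully out of frame")
  data.frame(frame = seq_len(config$n_frames) - 1L,
             dy_px = cum[, 1], dx_px = cum[, 2])
}

# Rasterize random line segments (smoothed) on a canvas: a crude but
# autocorrelated stand-in for an alveolar collagen mesh.
render_fiber_canvas <- function(h, w, n_fibers) {
  canvas <- matrix(0, h, w)
  for (i in seq_len(n_fibers)) {
    p0 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.1, 0.5) * min(h, w)
    amp <- stats::runif(1, 0.4, 1)
    tseq <- seq(0, len, by = 0.4)
    ys <- round(p0[1] + tseq * sin(ang)); xs <- round(p0[2] + tseq * cos(ang))
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    canvas[cbind(ys[ok], xs[ok])] <- pmax(canvas[cbind(ys[ok], xs[ok])], amp)
  }
  as.matrix(EBImage::gblur(EBImage::Image(canvas), sigma = 1.5))
}

#' Simulate the structural (collagen/SHG) channel
#'
#' Renders a single static fiber-mesh texture on a canvas larger than the
#' field by the drift range, then emits each frame as the field-of-view window
#' displaced by the negated cumulative drift — so frame content appears
#' translated *by* the drift, exactly as a drifting tissue would — plus
#' additive Gaussian noise.
#'
#' @param config an [simulation_config()].
#' @return list of `n_frames` image matrices.
#' @export
simulate_structural_channel <- function(config) {
  stopifnot(inherits(config, "rt_sim_config"))
  drift <- simulated_drift(config)
  h <- config$field_size_px[1]; w <- config$field_size_px[2]
  mgy <- max(abs(drift$dy_px)) + 1; mgx <- max(abs(drift$dx_px)) + 1
  canvas <- with_seed(config$seed + 2L,
                      render_fiber_canvas(h + 2 * mgy, w + 2 * mgx,
                                          config$n_fibers))
  frames <- lapply(seq_len(config$n_frames), function(t) {
    oy <- mgy - drift$dy_px[t]; ox <- mgx - drift$dx_px[t]
    canvas[(oy + 1):(oy + h), (ox + 1):(ox + w)]
  })
  if (config$noise_sd > 0)
    frames <- with_seed(config$seed + 3L,
                        lapply(frames, function(f)
                          f + matrix(stats::rnorm(h * w, sd = config$noise_sd),
                                     h, w)))
  frames
}

# Even-odd rasterization of a polygon given vertices in 0-based (x, y) pixel
# coordinates; returns the (row, col) indices of covered pixels within (h, w).
rasterize_polygon <- function(vx, vy, h, w) {
  x0 <- max(0L, floor(min(vx))); x1 <- min(w - 1L, ceiling(max(vx)))
  y0 <- max(0L, floor(min(vy))); y1 <- min(h - 1L, ceiling(max(vy)))
  if (x0 > x1 || y0 > y1) return(matrix(integer(0), 0, 2))
  px <- rep(x0:x1, each = y1 - y0 + 1)
  py <- rep(y0:y1, times = x1 - x0 + 1)
  inside <- rep(FALSE, length(px))
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  cbind(py[inside] + 1L, px[inside] + 1L)
}

# Star-polygon vertices for a dendritic cell: arms alternate with body radius.
star_vertices <- function(cx, cy, body_r, outer_r, n_arms, rot) {
  ang <- rot + seq(0, 2 * pi, length.out = 2 * n_arms + 1)[-(2 * n_arms + 1)]
  r <- rep(c(outer_r, body_r), n_arms)
  list(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

# Disk pixels: centres within radius of (cx, cy), 0-based coordinates.
rasterize_disk <- function(cx, cy, r, h, w) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(w - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(h - 1L, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(matrix(integer(0), 0, 2))
  px <- rep(x0:x1, each = y1 - y0 + 1)
  py <- rep(y0:y1, times = x1 - x0 + 1)
  keep <- (px - cx)^2 + (py - cy)^2 <= r^2
  cbind(py[keep] + 1L, px[keep] + 1L)
}

# Isotropic random walk with reflecting boundaries on [lo, hi] (per axis).
reflect <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

#' Simulate the fluorescent-cell channel with ground truth
#'
#' Places `n_round_cells` disks and `n_dendritic_cells` star polygons at
#' mutually separated random positions, walks each cell with a fixed step
#' length `speed * frame_interval` and uniform random heading (reflecting at
#' the field margins), renders every frame with the same cumulative drift as
#' the structural channel, and adds Gaussian noise. Ground-truth positions are
#' recorded *before* drift, in micrometres.
#'
#' @param config an [simulation_config()].
#' @return list with `frames` (list of image matrices), `truth` (data.frame
#'   `cell_id`, `frame`, `x_um`, `y_um`, `label`), `labels` (data.frame
#'   `cell_id`, `label`), and `drift` (as [simulated_drift()]).
#' @export
simulate_cell_channel <- function(config) {
  stopifnot(inherits(config, "rt_sim_config"))
  drift <- simulated_drift(config)
  h <- config$field_size_px[1]; w <- config$field_size_px[2]
  px <- config$pixel_size_um
  n_cells <- config$n_round_cells + config$n_dendritic_cells
  labels <- rep(c("round", "dendritic"),
                c(config$n_round_cells, config$n_dendritic_cells))

  extent_um <- max(config$round_radius_um,
                   config$dendritic_body_radius_um +
                     config$dendritic_arm_length_um)
  margin_um <- extent_um + 3 * px
  lo_x <- margin_um; hi_x <- (w - 1) * px - margin_um
  lo_y <- margin_um; hi_y <- (h - 1) * px - margin_um
  if (lo_x >= hi_x || lo_y >= hi_y)
    stop("field too small for the configured cell sizes")

  sim <- with_seed(config$seed + 4L, {
    # initial placement with minimum separation, by rejection
    pos <- matrix(NA_real_, n_cells, 2)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in 1:2000) {
        cand <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
        if (i == 1 || all(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE],
                                             2, cand)^2)) >=
                          config$min_separation_um)) {
          pos[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("cannot place cells with the configured minimum separation")
    }
    rot <- stats::runif(n_cells, 0, 2 * pi)
    speed <- ifelse(labels == "round", config$round_speed_um_min,
                    config$dendritic_speed_um_min)
    step <- speed * config$frame_interval_min

    xs <- matrix(NA_real_, config$n_frames, n_cells)
    ys <- matrix(NA_real_, config$n_frames, n_cells)
    xs[1, ] <- pos[, 1]; ys[1, ] <- pos[, 2]
    for (t in 2:config$n_frames) {
      heading <- stats::runif(n_cells, 0, 2 * pi)
      xs[t, ] <- reflect(xs[t - 1, ] + step * cos(heading), lo_x, hi_x)
      ys[t, ] <- reflect(ys[t - 1, ] + step * sin(heading), lo_y, hi_y)
    }
    list(xs = xs, ys = ys, rot = rot)
  })

  frames <- lapply(seq_len(config$n_frames), function(t) {
    f <- matrix(0, h, w)
    for (i in seq_len(n_cells)) {
      cx <- sim$xs[t, i] / px + drift$dx_px[t]
      cy <- sim$ys[t, i] / px + drift$dy_px[t]
      if (labels[i] == "round") {
        idx <- rasterize_disk(cx, cy, config$round_radius_um / px, h, w)
      } else {
        v <- star_vertices(cx, cy, config$dendritic_body_radius_um / px,
                           (config$dendritic_body_radius_um +
                              config$dendritic_arm_length_um) / px,
                           config$dendritic_arm_count, sim$rot[i])
        idx <- rasterize_polygon(v$x, v$y, h, w)
      }
      f[idx] <- 1
    }
    f
  })
  if (config$noise_sd > 0)
    frames <- with_seed(config$seed + 5L,
                        lapply(frames, function(f)
                          f + matrix(stats::rnorm(h * w, sd = config$noise_sd),
                                     h, w)))

  truth <- data.frame(
    cell_id = rep(seq_len(n_cells), each = config$n_frames),
    frame = rep(seq_len(config$n_frames) - 1L, n_cells),
    x_um = as.vector(sim$xs), y_um = as.vector(sim$ys),
    label = rep(labels, each = config$n_frames))
  list(frames = frames,
       truth = truth,
       labels = data.frame(cell_id = seq_len(n_cells), label = labels),
       drift = drift)
}

#' Simulate a complete two-channel movie with ground truth
#'
#' Convenience wrapper combining [simulate_structural_channel()] and
#' [simulate_cell_channel()] — both driven by the same drift — into an
#' [rt_movie()].
#'
#' @param config an [simulation_config()].
#' @return list with `movie` (an [rt_movie()]), `truth`, `labels`, `drift`.
#' @export
simulate_movie <- function(config) {
  shg <- simulate_structural_channel(config)
  cells <- simulate_cell_channel(config)
  list(movie = rt_movie(cells$frames, shg, config$pixel_size_um,
                        config$frame_interval_min),
       truth = cells$truth, labels = cells$labels, drift = cells$drift)
}

# One truncated-normal draw per element, truncated to [0, 1], by rejection.
rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) {
    if (any(mean <= 0 | mean >= 1))
      stop("irc_sd = 0 requires class means strictly inside (0, 1)")
    return(rep(mean, length.out = n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < 0 | out > 1)
  }
  out
}

#' Simulate a bare track table (image-free fixture)
#'
#' Emits per-frame positions and per-frame roundness values for two cell
#' classes without any rendering: each cell walks isotropically at its class
#' speed and draws its per-frame IRC from a class-specific normal distribution
#' truncated to \[0, 1\]. Useful for testing the metrics, classification and
#' statistics stages at scale.
#'
#' @param config an [simulation_config()] (field size, speeds, counts, seed).
#' @param irc_means length-2 numeric in (0, 1): IRC means for the dendritic
#'   and round classes, in that order (low mean = dendritic).
#' @param irc_sd common IRC standard deviation (>= 0).
#' @return list with `tracks` (data.frame `cell_id`, `frame`, `x_um`, `y_um`,
#'   `irc`) and `labels` (data.frame `cell_id`, `label`).
#' @export
simulate_track_table <- function(config, irc_means = c(0.25, 0.55),
                                 irc_sd = 0.05) {
  stopifnot(inherits(config, "rt_sim_config"),
            length(irc_means) == 2, all(irc_means > 0), all(irc_means < 1),
            irc_sd >= 0)
  n_cells <- config$n_round_cells + config$n_dendritic_cells
  labels <- rep(c("dendritic", "round"),
                c(config$n_dendritic_cells, config$n_round_cells))
  mean_of <- ifelse(labels == "dendritic", irc_means[1], irc_means[2])
  speed <- ifelse(labels == "dendritic", config$dendritic_speed_um_min,
                  config$round_speed_um_min)
  w_um <- (config$field_size_px[2] - 1) * config$pixel_size_um
  h_um <- (config$field_size_px[1] - 1) * config$pixel_size_um

  with_seed(config$seed + 6L, {
    step <- speed * config$frame_interval_min
    xs <- matrix(NA_real_, config$n_frames, n_cells)
    ys <- matrix(NA_real_, config$n_frames, n_cells)
    xs[1, ] <- stats::runif(n_cells, 0, w_um)
    ys[1, ] <- stats::runif(n_cells, 0, h_um)
    for (t in 2:config$n_frames) {
      heading <- stats::runif(n_cells, 0, 2 * pi)
      xs[t, ] <- reflect(xs[t - 1, ] + step * cos(heading), 0, w_um)
      ys[t, ] <- reflect(ys[t - 1, ] + step * sin(heading), 0, h_um)
    }
    irc <- vapply(seq_len(n_cells), function(i)
      rtruncnorm01(config$n_frames, mean_of[i], irc_sd),
      numeric(config$n_frames))
    list(tracks = data.frame(
      cell_id = rep(seq_len(n_cells), each = config$n_frames),
      frame = rep(seq_len(config$n_frames) - 1L, n_cells),
      x_um = as.vector(xs), y_um = as.vector(ys),
      irc = as.vector(irc)),
      labels = data.frame(cell_id = seq_len(n_cells), label = labels))
  })
}

#' Write simulation ground truth to CSV
#'
#' @param sim result of [simulate_movie()] or [simulate_cell_channel()].
#' @param dir output directory (created if missing).
#' @return paths of the written files (`truth.csv`, `drift.csv`), invisibly.
#' @export
write_ground_truth <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "truth.csv"); p2 <- file.path(dir, "drift.csv")
  utils::write.csv(sim$truth, p1, row.names = FALSE)
  utils::write.csv(sim$drift, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write / read a simulation config as plain text
#'
#' Serializes the config as `key: value` lines (pairs and matrices as
#' comma-separated values; the optional drift matrix as one `dy,dx` pair per
#' `drift_<frame>` key).
#'
#' @param config an [simulation_config()].
#' @param path file path.
#' @return `write_sim_config`: the path, invisibly. `read_sim_config`: an
#'   [simulation_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "rt_sim_config"))
  lines <- character(0)
  for (nm in names(config)) {
    v <- config[[nm]]
    if (is.null(v)) next
    if (nm == "drift") {
      for (t in seq_len(nrow(v)))
        lines <- c(lines, sprintf("drift_%d: %s", t - 1,
                                  paste(v[t, ], collapse = ",")))
    } else {
      lines <- c(lines, sprintf("%s: %s", nm,
                                paste(format(v, digits = 17), collapse = ",")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^:]+): *(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  parse_num <- function(s) as.numeric(strsplit(s, ",")[[1]])
  args <- list()
  drift_rows <- grepl("^drift_[0-9]+$", keys)
  if (any(drift_rows)) {
    ord <- order(as.integer(sub("drift_", "", keys[drift_rows])))
    args$drift <- do.call(rbind, lapply(vals[drift_rows][ord], parse_num))
  }
  for (i in which(!drift_rows)) args[[keys[i]]] <- parse_num(vals[i])
  do.call(simulation_config, args)
}
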