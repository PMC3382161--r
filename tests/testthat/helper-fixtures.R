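# Small simulation configs and independent oracles shared across tests.

# A compact movie config: 128 px field, short clip, separated cells.
small_config <- function(seed = 1, ...) {
  args <- list(field_size_px = c(128, 128), n_frames = 8, n_round_cells = 3,
               n_dendritic_cells = 2, min_separation_um = 15,
               round_radius_um = 4, dendritic_arm_length_um = 8,
               drift_sd_px = 2, n_fibers = 40, noise_sd = 0.02, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# Render a single disk in an otherwise empty frame (0-based centre coords).
disk_frame <- function(h, w, cx, cy, r) {
  f <- matrix(0, h, w)
  f[roundtrack:::rasterize_disk(cx, cy, r, h, w)] <- 1
  f
}

# Exhaustive frame-to-frame linker: at every frame, enumerate ALL injective
# assignments of open tracks to current detections within max_disp, keep the
# one with the most links and, among those, the least total squared
# displacement. Independent of the package's component/branch-and-bound
# solver.
oracle_link <- function(det, max_disp, min_len = 2) {
  det <- det[order(det$frame, det$x_um, det$y_um), , drop = FALSE]
  frames <- sort(unique(det$frame))
  last <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                     frame = integer(0))
  rows_of <- list(); next_id <- 1L
  for (f in frames) {
    rows <- which(det$frame == f)
    dx <- det$x_um[rows]; dy <- det$y_um[rows]
    act <- which(last$frame == f - 1)
    nt <- length(act); nd <- length(rows)
    best <- list(m = -1L, cost = Inf, asg = rep(NA_integer_, nt))
    asg <- rep(NA_integer_, nt)
    rec <- function(k, m, cost, used) {
      if (k > nt) {
        if (m > best$m || (m == best$m && cost < best$cost))
          best <<- list(m = m, cost = cost, asg = asg)
        return()
      }
      a <- act[k]
      for (j in seq_len(nd)) {
        if (used[j]) next
        d2 <- (dx[j] - last$x[a])^2 + (dy[j] - last$y[a])^2
        if (d2 > max_disp^2) next
        asg[k] <<- j
        used2 <- used; used2[j] <- TRUE
        rec(k + 1L, m + 1L, cost + d2, used2)
        asg[k] <<- NA_integer_
      }
      rec(k + 1L, m, cost, used)
    }
    rec(1L, 0L, 0, rep(FALSE, nd))
    taken <- rep(FALSE, nd)
    for (k in seq_len(nt)) {
      j <- best$asg[k]
      if (is.na(j)) next
      a <- act[k]; id <- last$id[a]
      rows_of[[id]] <- c(rows_of[[id]], rows[j])
      last$x[a] <- dx[j]; last$y[a] <- dy[j]; last$frame[a] <- f
      taken[j] <- TRUE
    }
    for (j in which(!taken)) {
      rows_of[[next_id]] <- rows[j]
      last <- rbind(last, data.frame(id = next_id, x = dx[j], y = dy[j],
                                     frame = f))
      next_id <- next_id + 1L
    }
  }
  keep <- which(lengths(rows_of) >= min_len)
  lapply(keep, function(i) {
    tr <- det[rows_of[[i]], c("frame", "x_um", "y_um")]
    tr[order(tr$frame), , drop = FALSE]
  })
}

# Canonical string form of a set of tracks, for set comparison.
track_set_signature <- function(track_list) {
  sigs <- vapply(track_list, function(tr)
    paste(sprintf("%d:%.6f:%.6f", tr$frame, tr$x_um, tr$y_um),
          collapse = "|"),
    character(1))
  sort(unname(sigs))
}

# Split a linked-detections data.frame into the same canonical form.
linked_to_track_list <- function(linked) {
  lapply(split(linked, linked$track_id), function(tr) {
    tr <- tr[order(tr$frame), c("frame", "x_um", "y_um")]
    rownames(tr) <- NULL
    tr
  })
}

# Random linking instance: n_cells random walkers, some detections deleted.
random_link_instance <- function(seed, max_cells = 5, max_frames = 6) {
  set.seed(seed)
  nc <- sample(2:max_cells, 1)
  nf <- sample(3:max_frames, 1)
  pos <- matrix(runif(2 * nc, 5, 45), nc, 2)
  rows <- list()
  for (f in 0:(nf - 1)) {
    pos <- pos + matrix(rnorm(2 * nc, sd = 3), nc, 2)
    keep <- runif(nc) > 0.1   # occasional missed detection
    if (any(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, x_um = pos[keep, 1], y_um = pos[keep, 2],
        irc = runif(sum(keep)))
  }
  do.call(rbind, rows)
}
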