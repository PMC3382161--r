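#' Linking parameters for multiple-particle tracking
#'
#' @param max_displacement_um maximum distance a cell may move between
#'   consecutive frames to be considered the same cell. Default 20 um (10
#'   um/min at 2-min sampling), comfortably above typical lung immune-cell
#'   speeds.
#' @param memory_frames number of consecutive missing frames a track may
#'   bridge (a cell lost to segmentation for up to this many frames keeps its
#'   identity).
#' @param min_track_length minimum number of observed detections for a track
#'   to be kept.
#' @return a list of class `rt_link_params`.
#' @export
linking_params <- function(max_displacement_um = 20, memory_frames = 1L,
                           min_track_length = 3L) {
  stopifnot(max_displacement_um > 0, memory_frames >= 0,
            min_track_length >= 2)
  structure(list(max_displacement_um = max_displacement_um,
                 memory_frames = as.integer(memory_frames),
                 min_track_length = as.integer(min_track_length)),
            class = "rt_link_params")
}

# Optimal one-to-one assignment between track endpoints and detections:
# maximize the number of links, then minimize total squared displacement
# (the Crocker-Grier criterion). `edges` is a list per track of candidate
# detection indices; `cost` the matching squared distances. Solved exactly by
# branch-and-bound within each connected component of the candidate graph.
assign_links <- function(n_tracks, n_dets, edges, costs) {
  assignment <- rep(NA_integer_, n_tracks)
  if (n_tracks == 0L || n_dets == 0L) return(assignment)

  # connected components over the bipartite candidate graph
  comp_t <- rep(0L, n_tracks); comp_d <- rep(0L, n_dets); nc <- 0L
  det_tracks <- vector("list", n_dets)
  for (i in seq_len(n_tracks))
    for (j in edges[[i]]) det_tracks[[j]] <- c(det_tracks[[j]], i)
  for (s in seq_len(n_tracks)) {
    if (comp_t[s] != 0L || length(edges[[s]]) == 0L) next
    nc <- nc + 1L
    stack <- list(c(1L, s))  # (1 = track, 2 = det)
    while (length(stack) > 0) {
      nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (nd[1] == 1L) {
        i <- nd[2]
        if (comp_t[i] != 0L) next
        comp_t[i] <- nc
        for (j in edges[[i]]) if (comp_d[j] == 0L)
          stack[[length(stack) + 1L]] <- c(2L, j)
      } else {
        j <- nd[2]
        if (comp_d[j] != 0L) next
        comp_d[j] <- nc
        for (i in det_tracks[[j]]) if (comp_t[i] == 0L)
          stack[[length(stack) + 1L]] <- c(1L, i)
      }
    }
  }

  for (c_id in seq_len(nc)) {
    tr <- which(comp_t == c_id)
    best <- list(matches = -1L, cost = Inf, asg = NULL)
    asg <- rep(NA_integer_, length(tr))
    used <- rep(FALSE, n_dets)
    recurse <- function(k, matches, cost) {
      remaining <- length(tr) - k + 1L
      if (matches + remaining < best$matches) return()
      if (k > length(tr)) {
        if (matches > best$matches ||
            (matches == best$matches && cost < best$cost))
          best <<- list(matches = matches, cost = cost, asg = asg)
        return()
      }
      i <- tr[k]
      cand <- edges[[i]]
      ord <- order(costs[[i]])
      for (m in ord) {
        j <- cand[m]
        if (used[j]) next
        used[j] <<- TRUE; asg[k] <<- j
        recurse(k + 1L, matches + 1L, cost + costs[[i]][m])
        used[j] <<- FALSE; asg[k] <<- NA_integer_
      }
      recurse(k + 1L, matches, cost)  # leave this track unmatched
    }
    recurse(1L, 0L, 0)
    assignment[tr] <- best$asg
  }
  assignment
}

#' Link per-frame detections into cell tracks
#'
#' Frame-to-frame nearest-assignment linking in the style of the classical
#' multiple-particle tracking codes: among all one-to-one pairings of open
#' track ends with current-frame detections lying within
#' `max_displacement_um * (frame gap)`, the pairing that links the most cells
#' and, among those, minimizes the total squared displacement is chosen
#' (solved exactly per connected component of the candidate graph). Unmatched
#' detections open new tracks; a track missing from up to `memory_frames`
#' consecutive frames may be bridged; shorter tracks than `min_track_length`
#' are discarded. Track ids are assigned in order of first appearance, and
#' within-frame detection order does not affect the result.
#'
#' @param detections data.frame with columns `frame` (integer), `x_um`,
#'   `y_um`, plus any extra columns (e.g. `irc`), typically from
#'   [detect_movie()].
#' @param params a [linking_params()].
#' @return the detections that belong to retained tracks, with a `track_id`
#'   column prepended, ordered by `track_id` then `frame`.
#' @export
link_detections <- function(detections, params = linking_params()) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_um", "y_um") %in% names(detections)),
            inherits(params, "rt_link_params"))
  if (nrow(detections) == 0L) {
    out <- cbind(track_id = integer(0), detections)
    return(out)
  }
  det <- detections[order(detections$frame, detections$x_um,
                          detections$y_um), , drop = FALSE]
  frames <- sort(unique(det$frame))

  track_last <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                           frame = integer(0))
  track_rows <- list()   # per id: row indices into det
  next_id <- 1L

  for (f in frames) {
    rows <- which(det$frame == f)
    dx <- det$x_um[rows]; dy <- det$y_um[rows]
    nd <- length(rows)

    active <- which(f - track_last$frame >= 1 &
                      f - track_last$frame <= params$memory_frames + 1L)
    edges <- vector("list", length(active))
    costs <- vector("list", length(active))
    for (k in seq_along(active)) {
      a <- active[k]
      gap <- f - track_last$frame[a]
      lim2 <- (params$max_displacement_um * gap)^2
      d2 <- (dx - track_last$x[a])^2 + (dy - track_last$y[a])^2
      ok <- which(d2 <= lim2)
      edges[[k]] <- ok
      costs[[k]] <- d2[ok]
    }
    asg <- assign_links(length(active), nd, edges, costs)

    matched_dets <- rep(FALSE, nd)
    for (k in seq_along(active)) {
      j <- asg[k]
      if (is.na(j)) next
      a <- active[k]
      id <- track_last$id[a]
      track_rows[[id]] <- c(track_rows[[id]], rows[j])
      track_last$x[a] <- dx[j]; track_last$y[a] <- dy[j]
      track_last$frame[a] <- f
      matched_dets[j] <- TRUE
    }
    for (j in which(!matched_dets)) {
      track_rows[[next_id]] <- rows[j]
      track_last <- rbind(track_last,
                          data.frame(id = next_id, x = dx[j], y = dy[j],
                                     frame = f))
      next_id <- next_id + 1L
    }
  }

  keep <- which(lengths(track_rows) >= params$min_track_length)
  if (length(keep) == 0L) {
    out <- cbind(track_id = integer(0), det[0, , drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  # dense ids in order of first appearance (creation order == id order)
  pieces <- lapply(seq_along(keep), function(i) {
    r <- track_rows[[keep[i]]]
    cbind(track_id = i, det[r, , drop = FALSE])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Summarize tracks
#'
#' One row per track with its frame span and two time measures:
#' `duration_min`, the elapsed time between the first and last observation
#' (`(n - 1) * frame_interval`), and `observation_time_min`, the per-frame
#' observation time (`n * frame_interval`, the convention under which a cell
#' followed on 16 two-minute frames is reported as observed for 32 minutes).
#'
#' @param tracks data.frame with `track_id` and `frame` columns (from
#'   [link_detections()]).
#' @param frame_interval_min minutes between consecutive frames.
#' @return data.frame with columns `track_id`, `first_frame`, `last_frame`,
#'   `n_frames_observed`, `duration_min`, `observation_time_min`.
#' @export
track_summary <- function(tracks, frame_interval_min = 2) {
  stopifnot(is.data.frame(tracks), frame_interval_min > 0)
  if (nrow(tracks) == 0L)
    return(data.frame(track_id = integer(0), first_frame = integer(0),
                      last_frame = integer(0), n_frames_observed = integer(0),
                      duration_min = numeric(0),
                      observation_time_min = numeric(0)))
  ids <- sort(unique(tracks$track_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    fr <- tracks$frame[tracks$track_id == id]
    n <- length(fr)
    data.frame(track_id = id, first_frame = min(fr), last_frame = max(fr),
               n_frames_observed = n,
               duration_min = (n - 1) * frame_interval_min,
               observation_time_min = n * frame_interval_min)
  }))
  rownames(out) <- NULL
  out
}
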