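#' Mean Roundness Coefficient of a track
#'
#' Arithmetic mean of the per-frame Instantaneous Roundness Coefficients over
#' the frames on which the cell was observed — the feature on which
#' dendritic-shaped and round-shaped cells are discriminated.
#'
#' @param irc numeric vector of per-frame IRC values (one per observed frame).
#' @return the mean roundness, in \[0, 1\].
#' @export
mean_roundness <- function(irc) {
  if (length(irc) == 0L) stop("track has no IRC observations")
  mean(irc)
}

#' Maximal Distance of a track
#'
#' The greatest Euclidean distance a cell reaches from its first recorded
#' position — a measure of how far a cell explores, insensitive to the path
#' taken.
#'
#' @param x,y numeric vectors of positions (um), time-ordered.
#' @return maximal distance in um (0 for a single point).
#' @export
maximal_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  max(sqrt((x - x[1])^2 + (y - y[1])^2))
}

#' Meandering Index of a track
#'
#' Final displacement from the first position divided by the total path
#' length: 1 for a perfectly straight path, near 0 for confined or returning
#' motion. A stationary track (zero path length) is assigned 0 rather than
#' left undefined, so such cells are retained; callers can detect them via the
#' path length.
#'
#' @inheritParams maximal_distance
#' @return meandering index in \[0, 1\].
#' @export
meandering_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  pl <- path_length(x, y)
  if (pl == 0) return(0)
  n <- length(x)
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) / pl
}

#' Total path length of a track
#'
#' Sum of Euclidean lengths of consecutive segments. A bridged detection gap
#' contributes a single straight-line segment.
#'
#' @inheritParams maximal_distance
#' @return path length in um.
#' @export
path_length <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (length(x) == 1L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Mean velocity of a track
#'
#' Total path length divided by the elapsed observation time
#' `(last frame - first frame) * frame_interval` — the mean instantaneous
#' speed. (The alternative, displacement over time, equals this velocity
#' multiplied by the meandering index.)
#'
#' @inheritParams maximal_distance
#' @param frame integer vector of frame indices, time-ordered.
#' @param frame_interval_min minutes per frame step.
#' @return velocity in um/min.
#' @export
track_velocity <- function(x, y, frame, frame_interval_min = 2) {
  stopifnot(length(x) >= 2, length(x) == length(y),
            length(x) == length(frame))
  dur <- (frame[length(frame)] - frame[1]) * frame_interval_min
  if (dur <= 0) stop("track has zero duration")
  path_length(x, y) / dur
}

#' Per-track motility and shape metrics
#'
#' Computes, for every track, the four headline quantities — Mean Roundness
#' Coefficient (MRC), Maximal Distance (MD), Meandering Index (MI) and
#' velocity — plus the final displacement, path length and frame count.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`, `y_um`,
#'   `irc` (from [link_detections()]).
#' @param frame_interval_min minutes between consecutive frames.
#' @return data.frame with one row per track: `track_id`, `mrc`, `md_um`,
#'   `mi`, `final_displacement_um`, `path_length_um`, `velocity_um_min`,
#'   `n_frames_observed`, `stationary` (logical flag for zero-path tracks,
#'   whose MI is reported as 0).
#' @export
track_metrics <- function(tracks, frame_interval_min = 2) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_um", "y_um", "irc") %in%
                  names(tracks)))
  ids <- sort(unique(tracks$track_id))
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    pl <- path_length(tr$x_um, tr$y_um)
    fd <- sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2)
    data.frame(
      track_id = id,
      mrc = mean_roundness(tr$irc),
      md_um = maximal_distance(tr$x_um, tr$y_um),
      mi = if (n >= 2) meandering_index(tr$x_um, tr$y_um) else 0,
      final_displacement_um = fd,
      path_length_um = pl,
      velocity_um_min = if (n >= 2)
        track_velocity(tr$x_um, tr$y_um, tr$frame, frame_interval_min)
      else 0,
      n_frames_observed = n,
      stationary = pl == 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
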