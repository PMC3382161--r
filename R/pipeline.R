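#' Run the full shape-based tracking pipeline on a movie
#'
#' Chains the analysis stages: drift correction from the structural channel,
#' cell segmentation with roundness scoring, track linking, per-track motility
#' metrics, and shape classification. Classification uses the supplied fixed
#' MRC threshold by default (0.35, the standard operating value); with
#' `mrc_threshold = NULL` a double-Gaussian fit of the MRC histogram supplies
#' the threshold (this requires enough tracks for a bimodal histogram).
#'
#' @param movie an [rt_movie()].
#' @param seg_params a [segmentation_params()].
#' @param link_params a [linking_params()].
#' @param max_shift_px maximum per-step drift searched.
#' @param mrc_threshold fixed MRC threshold, or `NULL` to fit one.
#' @param bin_width histogram bin width used when fitting the threshold.
#' @return list with `drift`, `detections`, `tracks`, `summary`, `metrics`,
#'   `classification` (see [classify_tracks()]), `fit` (the mixture fit or
#'   `NULL`), and `aligned` (the drift-corrected movie).
#' @export
run_pipeline <- function(movie, seg_params = segmentation_params(),
                         link_params = linking_params(),
                         max_shift_px = 50, mrc_threshold = 0.35,
                         bin_width = 0.05) {
  reg <- correct_drift(movie, max_shift_px = max_shift_px)
  detections <- detect_movie(reg$movie, seg_params)
  tracks <- link_detections(detections, link_params)
  metrics <- track_metrics(tracks, movie$frame_interval_min)
  fit <- NULL
  if (is.null(mrc_threshold)) {
    h <- build_mrc_histogram(metrics$mrc, bin_width)
    fit <- fit_double_gaussian(h$bin_edges, h$bin_counts)
    mrc_threshold <- fit$threshold
  }
  classification <- classify_tracks(metrics, mrc_threshold)
  list(drift = reg$drift, detections = detections, tracks = tracks,
       summary = track_summary(tracks, movie$frame_interval_min),
       metrics = metrics, classification = classification, fit = fit,
       aligned = reg$movie)
}

#' Match output tracks to simulated ground-truth cells
#'
#' Assigns each reconstructed track to the ground-truth cell whose true
#' positions are closest on average over the track's observed frames — the
#' bookkeeping needed to score label agreement and identity switches against
#' a simulation.
#'
#' @param tracks data.frame from [link_detections()] (`track_id`, `frame`,
#'   `x_um`, `y_um`).
#' @param truth ground-truth data.frame (`cell_id`, `frame`, `x_um`, `y_um`,
#'   `label`) as produced by [simulate_cell_channel()].
#' @return data.frame with one row per track: `track_id`, `cell_id`,
#'   `mean_dist_um` (mean distance to the matched cell over common frames),
#'   `true_label`.
#' @export
match_tracks_to_truth <- function(tracks, truth) {
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)),
            all(c("cell_id", "frame", "x_um", "y_um", "label") %in%
                  names(truth)))
  ids <- sort(unique(tracks$track_id))
  cells <- sort(unique(truth$cell_id))
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    dists <- vapply(cells, function(cid) {
      tc <- truth[truth$cell_id == cid, , drop = FALSE]
      j <- match(tr$frame, tc$frame)
      if (anyNA(j)) return(Inf)
      mean(sqrt((tr$x_um - tc$x_um[j])^2 + (tr$y_um - tc$y_um[j])^2))
    }, numeric(1))
    k <- which.min(dists)
    data.frame(track_id = id, cell_id = cells[k], mean_dist_um = dists[k],
               true_label = truth$label[truth$cell_id == cells[k]][1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
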