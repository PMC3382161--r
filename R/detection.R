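#' Instantaneous Roundness Coefficient
#'
#' Circularity of a single object: `4 * pi * area / perimeter^2`, the classical
#' isoperimetric shape index. It is 1 for an ideal circle and tends to 0 as a
#' shape elongates towards a line, so it separates round cell bodies from
#' dendritiform cells with radiating protrusions. Digital perimeter estimators
#' can overshoot slightly for near-circular masks, so the value is clamped to
#' \[0, 1\].
#'
#' @param area object area (any consistent unit of length squared).
#' @param perimeter object perimeter (same length unit).
#' @return the roundness coefficient, a value in \[0, 1\].
#' @examples
#' compute_irc(pi * 5^2, 2 * pi * 5)  # ideal circle -> 1
#' compute_irc(4, 8)                  # unit square scaled: pi/4
#' @export
compute_irc <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be strictly positive")
  pmin(pmax(4 * pi * area / perimeter^2, 0), 1)
}

#' Perimeter of a binary mask by the Cauchy-Crofton intercept count
#'
#' Estimates the boundary length of a digital object from the number of
#' foreground/background transitions along four families of parallel lines
#' (rows, columns and both diagonals), weighting each family by its line
#' spacing:
#' `P = (pi / 8) * sum_theta n_theta * s_theta`
#' with `s = 1` for the axis directions and `s = 1 / sqrt(2)` for the
#' diagonals. Compared to counting boundary pixels, this estimator has far
#' lower digitization bias, which keeps the roundness of rasterized disks
#' close to (and never far above) 1.
#'
#' @param mask logical or 0/1 matrix; `TRUE`/nonzero is foreground.
#' @return estimated perimeter in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  m <- (mask != 0) * 1L
  if (sum(m) == 0L) return(0)
  trans <- function(v) sum(abs(diff(c(0L, v, 0L))))
  n_rows <- sum(apply(m, 1, trans))
  n_cols <- sum(apply(m, 2, trans))
  d1 <- split(m, col(m) - row(m))     # 45-degree diagonals
  d2 <- split(m, col(m) + row(m))     # 135-degree diagonals
  n_d1 <- sum(vapply(d1, trans, numeric(1)))
  n_d2 <- sum(vapply(d2, trans, numeric(1)))
  (pi / 8) * (n_rows + n_cols + (n_d1 + n_d2) / sqrt(2))
}

#' Segmentation parameters
#'
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma in pixels (0 turns
#'   smoothing off).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity threshold, required iff
#'   `threshold_method = "fixed"`.
#' @param min_area_um2,max_area_um2 components outside this area range are
#'   discarded.
#' @param fill_holes fill interior holes of each component before measuring?
#' @param intensity_weighted_centroid use intensity-weighted rather than
#'   binary-mask centroids?
#' @return a list of class `rt_seg_params`.
#' @export
segmentation_params <- function(smoothing_sigma_px = 1,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area_um2 = 10, max_area_um2 = 1500,
                                fill_holes = TRUE,
                                intensity_weighted_centroid = FALSE) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold is required when threshold_method = 'fixed'")
  if (threshold_method == "otsu" && !is.null(fixed_threshold))
    stop("fixed_threshold must be NULL when threshold_method = 'otsu'")
  if (smoothing_sigma_px < 0) stop("smoothing_sigma_px must be >= 0")
  if (!(min_area_um2 > 0) || !(min_area_um2 < max_area_um2))
    stop("need 0 < min_area_um2 < max_area_um2")
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 fill_holes = fill_holes,
                 intensity_weighted_centroid = intensity_weighted_centroid),
            class = "rt_seg_params")
}

# Merge 4-connected labels that touch diagonally so components obey
# 8-connectivity. Works on the small set of label ids with union-find.
merge_diagonal_labels <- function(lab) {
  nl <- max(lab)
  if (nl < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Segment fluorescent cells in one frame and score their roundness
#'
#' Smooths the image, binarizes it (Otsu or a fixed threshold), optionally
#' fills holes, labels 8-connected components, discards components outside the
#' configured area range or touching the image border (truncated shapes would
#' corrupt the roundness estimate), and measures each surviving component:
#' binary-mask centroid, area, Crofton perimeter and Instantaneous Roundness
#' Coefficient.
#'
#' @param frame single-channel 2D numeric matrix.
#' @param params a [segmentation_params()] object.
#' @param pixel_size_um micrometres per pixel; converts pixel measurements to
#'   physical units.
#' @param frame_index 0-based frame index stored in the output.
#' @return a data.frame with one row per detected cell, columns `frame`,
#'   `x_um`, `y_um` (0-based pixel-centre coordinates scaled to um),
#'   `area_um2`, `perimeter_um`, `irc`, `pixel_count`, sorted by `x_um` then
#'   `y_um`. An all-background frame yields zero rows.
#' @export
segment_cells <- function(frame, params = segmentation_params(),
                          pixel_size_um = 280 / 512, frame_index = 0L) {
  stopifnot(is.matrix(frame), inherits(params, "rt_seg_params"))
  empty <- data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      irc = numeric(0), pixel_count = integer(0))

  img <- frame
  if (params$smoothing_sigma_px > 0) {
    # EBImage's Gaussian brush must fit inside the image
    radius <- 2 * ceiling(3 * params$smoothing_sigma_px) + 1
    radius <- min(radius, 2 * floor((min(dim(img)) - 1) / 2) + 1)
    if (radius >= 3)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                      sigma = params$smoothing_sigma_px,
                                      radius = radius))
  }
  if (params$threshold_method == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0) return(empty)
    th <- EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng)))
    mask <- (img - rng[1]) / diff(rng) > th
  } else {
    mask <- img > params$fixed_threshold
  }
  if (!any(mask)) return(empty)
  mask <- mask * 1
  if (params$fill_holes) mask <- as.matrix(EBImage::fillHull(mask))
  lab <- merge_diagonal_labels(as.matrix(EBImage::bwlabel(mask)))
  nl <- max(lab)
  if (nl == 0L) return(empty)

  # drop border-touching components
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(seq_len(nl), border)
  if (length(keep) == 0L) return(empty)

  px_area <- pixel_size_um^2
  rows <- lapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    npx <- nrow(idx)
    area <- npx * px_area
    if (area < params$min_area_um2 || area > params$max_area_um2)
      return(NULL)
    if (params$intensity_weighted_centroid) {
      wts <- frame[idx]
      if (sum(wts) <= 0) wts <- rep(1, npx)
      cy <- sum((idx[, 1] - 1) * wts) / sum(wts)
      cx <- sum((idx[, 2] - 1) * wts) / sum(wts)
    } else {
      cy <- mean(idx[, 1] - 1)
      cx <- mean(idx[, 2] - 1)
    }
    sub <- lab[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
               drop = FALSE]
    per_px <- crofton_perimeter(sub == l)
    per <- per_px * pixel_size_um
    data.frame(frame = as.integer(frame_index),
               x_um = cx * pixel_size_um, y_um = cy * pixel_size_um,
               area_um2 = area, perimeter_um = per,
               irc = compute_irc(area, per), pixel_count = npx)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$x_um, out$y_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect cells in every frame of an aligned movie
#'
#' Runs [segment_cells()] on the cell channel of each frame.
#'
#' @param movie an [rt_movie()], normally drift-corrected.
#' @param params a [segmentation_params()].
#' @return a data.frame of detections across all frames (see
#'   [segment_cells()]).
#' @export
detect_movie <- function(movie, params = segmentation_params()) {
  stopifnot(inherits(movie, "rt_movie"))
  out <- lapply(seq_len(n_frames(movie)), function(t)
    segment_cells(movie$cell[[t]], params, movie$pixel_size_um,
                  frame_index = t - 1L))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
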