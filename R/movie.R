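#' Two-channel time-lapse movie container
#'
#' Bundles a time-ordered sequence of two-channel 2D frames with spatial and
#' temporal calibration. Each frame holds a fluorescent-cell channel and a
#' structural channel (second-harmonic collagen signal) of identical size.
#' Matrices are indexed `[row = y, col = x]`, origin at the top-left pixel,
#' 0-based pixel-centre coordinates for all centroid output.
#'
#' @param cell list of numeric matrices, the fluorescent-cell channel frames.
#' @param structural list of numeric matrices, the structural (SHG) channel
#'   frames; same length and dimensions as `cell`.
#' @param pixel_size_um physical size of one pixel edge in micrometres.
#'   Default `280/512`, i.e. a 280 um field imaged at 512 px.
#' @param frame_interval_min time between consecutive frames in minutes.
#' @return An object of class `rt_movie`: a list with elements `cell`,
#'   `structural`, `pixel_size_um`, `frame_interval_min`.
#' @export
rt_movie <- function(cell, structural, pixel_size_um = 280 / 512,
                     frame_interval_min = 2) {
  stopifnot(is.list(cell), is.list(structural))
  if (length(cell) != length(structural))
    stop("cell and structural channels must have the same number of frames")
  if (length(cell) < 1L) stop("a movie needs at least one frame")
  d <- dim(cell[[1]])
  ok <- vapply(c(cell, structural),
               function(f) is.matrix(f) && identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical dimensions")
  if (!(pixel_size_um > 0) || !(frame_interval_min > 0))
    stop("calibration values must be strictly positive")
  structure(list(cell = cell, structural = structural,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "rt_movie")
}

#' @export
print.rt_movie <- function(x, ...) {
  d <- dim(x$cell[[1]])
  cat(sprintf("rt_movie: %d frames, %d x %d px, %.4f um/px, %.1f min/frame\n",
              length(x$cell), d[1], d[2], x$pixel_size_um,
              x$frame_interval_min))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie an [rt_movie()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) length(movie$cell)

#' Maximum intensity projection of a z-stack
#'
#' Collapses a 3D stack to a 2D image by taking the per-pixel maximum over the
#' z axis, the standard reduction applied to two-photon z-stacks before 2D
#' tracking analysis.
#'
#' @param zstack a 3D numeric array `[y, x, z]`, or a list of equally sized
#'   2D matrices (one per z slice).
#' @return a 2D matrix with the slice dimensions.
#' @export
max_project <- function(zstack) {
  if (is.list(zstack)) {
    if (length(zstack) == 0L) stop("empty z-stack")
    d <- dim(zstack[[1]])
    out <- zstack[[1]]
    for (s in zstack[-1]) {
      if (!identical(dim(s), d)) stop("z slices must share dimensions")
      out <- pmax(out, s)
    }
    return(out)
  }
  if (!is.array(zstack) || length(dim(zstack)) != 3L)
    stop("zstack must be a 3D array or a list of matrices")
  if (dim(zstack)[3] == 0L) stop("empty z-stack")
  apply(zstack, c(1, 2), max)
}

# Translate an image by an integer pixel shift (dy, dx); content moves down by
# dy rows and right by dx columns; exposed pixels are zero-filled.
translate_int <- function(img, dy, dx) {
  stopifnot(dy == round(dy), dx == round(dx))
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  ys <- seq_len(h) - dy   # source rows
  xs <- seq_len(w) - dx
  yok <- ys >= 1 & ys <= h
  xok <- xs >= 1 & xs <= w
  if (any(yok) && any(xok))
    out[which(yok), which(xok)] <- img[ys[yok], xs[xok]]
  out
}

#' Write a movie to multi-page TIFF
#'
#' Writes one multi-page TIFF per channel (or a single interleaved file with
#' cell and structural frames alternating) with intensities clipped to
#' \[0, 1\], the range the tiff writer expects.
#'
#' @param movie an [rt_movie()].
#' @param path output path for `interleaved = TRUE`, or a base path to which
#'   `_cell.tif` / `_shg.tif` are appended otherwise.
#' @param interleaved write a single file with alternating channels?
#' @return the written file path(s), invisibly.
#' @export
write_movie_tiff <- function(movie, path, interleaved = FALSE) {
  clip <- function(f) pmin(pmax(f, 0), 1)
  if (interleaved) {
    pages <- vector("list", 2L * n_frames(movie))
    pages[seq(1, length(pages), by = 2)] <- lapply(movie$cell, clip)
    pages[seq(2, length(pages), by = 2)] <- lapply(movie$structural, clip)
    tiff::writeTIFF(pages, path)
    return(invisible(path))
  }
  p1 <- paste0(path, "_cell.tif"); p2 <- paste0(path, "_shg.tif")
  tiff::writeTIFF(lapply(movie$cell, clip), p1)
  tiff::writeTIFF(lapply(movie$structural, clip), p2)
  invisible(c(p1, p2))
}

#' Read a movie from multi-page TIFF
#'
#' Counterpart of [write_movie_tiff()].
#'
#' @param cell_path path to the cell-channel TIFF, or to the interleaved file.
#' @param structural_path path to the structural-channel TIFF; omit for an
#'   interleaved file.
#' @param interleaved is `cell_path` a two-channel interleaved file?
#' @inheritParams rt_movie
#' @return an [rt_movie()].
#' @export
read_movie_tiff <- function(cell_path, structural_path = NULL,
                            interleaved = FALSE, pixel_size_um = 280 / 512,
                            frame_interval_min = 2) {
  as_mat <- function(x) { x <- as.matrix(x); dim(x) <- dim(x)[1:2]; x }
  if (interleaved) {
    pages <- tiff::readTIFF(cell_path, all = TRUE)
    pages <- lapply(pages, as_mat)
    idx <- seq_along(pages)
    return(rt_movie(pages[idx %% 2 == 1], pages[idx %% 2 == 0],
                    pixel_size_um, frame_interval_min))
  }
  rt_movie(lapply(tiff::readTIFF(cell_path, all = TRUE), as_mat),
           lapply(tiff::readTIFF(structural_path, all = TRUE), as_mat),
           pixel_size_um, frame_interval_min)
}
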