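#' Estimate the rigid shift between two images by normalized cross-correlation
#'
#' Finds the integer translation `(dy, dx)` of `moving` that best aligns it
#' with `reference`, by maximizing the normalized cross-correlation (zero-mean,
#' unit-variance over the overlap window) across all integer shifts with
#' `|dy|, |dx| <= max_shift_px`. The correlation surface is computed with the
#' standard FFT decomposition of windowed sums (Lewis' fast normalized
#' cross-correlation), so the search is exhaustive but not quadratic in image
#' size.
#'
#' A positive `dy`/`dx` means the content of `moving` sits `dy` rows down and
#' `dx` columns right of where it sits in `reference`; translating `moving` by
#' `(-dy, -dx)` aligns it.
#'
#' @param reference,moving 2D numeric matrices of identical dimensions.
#' @param max_shift_px maximum absolute shift searched, in pixels.
#' @param subpixel if `TRUE`, refine the integer peak by parabolic
#'   interpolation of the correlation surface (default off; the returned shift
#'   is then fractional).
#' @param min_overlap_frac minimum fraction of the image area that must remain
#'   in the overlap window for a shift to be considered (guards against
#'   spurious maxima from tiny overlaps).
#' @return list with `shift` (numeric `(dy, dx)`) and `peak_correlation`
#'   (the normalized cross-correlation at the optimum, in \[-1, 1\]).
#' @export
estimate_shift <- function(reference, moving, max_shift_px = 50,
                           subpixel = FALSE, min_overlap_frac = 0.25) {
  stopifnot(is.matrix(reference), is.matrix(moving))
  if (!identical(dim(reference), dim(moving)))
    stop("reference and moving images must have identical dimensions")
  if (max_shift_px < 0) stop("max_shift_px must be >= 0")
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("constant image: registration by cross-correlation is ill-posed")

  h <- nrow(reference); w <- ncol(reference)
  ms <- min(max_shift_px, h - 1L, w - 1L)

  # FFT size with padding so circular correlation has no wrap-around within
  # the searched shift range.
  ph <- h + ms; pw <- w + ms
  pad <- function(x) { out <- matrix(0, ph, pw); out[1:h, 1:w] <- x; out }
  one <- pad(matrix(1, h, w))
  R <- pad(reference); M <- pad(moving)

  F1 <- stats::fft(R); F2 <- stats::fft(M); Fo <- stats::fft(one)
  F1s <- stats::fft(R^2); F2s <- stats::fft(M^2)
  # xcorr(A, B)[k] = sum_n A[n] * B[n - k]: with A the moving image, the
  # argmax index k is the shift that moved the content (moving[n] = ref[n - k])
  xcorr <- function(A, B)
    Re(stats::fft(A * Conj(B), inverse = TRUE)) / (ph * pw)

  s_rm <- xcorr(F2, F1)    # sum moving * back-shifted ref over overlap
  s_m  <- xcorr(F2, Fo)    # sum moving over overlap
  s_r  <- xcorr(Fo, F1)    # sum ref over overlap
  s_m2 <- xcorr(F2s, Fo)
  s_r2 <- xcorr(Fo, F1s)
  n_ov <- xcorr(Fo, Fo)    # overlap pixel count

  # index (i, j) of the correlation arrays corresponds to shift
  # dy = ((i - 1 + ms) mod ph) - ms, same for dx; restrict to the window.
  idx_of <- function(s, np) ((s %% np) + np) %% np + 1L
  dys <- -ms:ms; dxs <- -ms:ms
  ii <- idx_of(dys, ph); jj <- idx_of(dxs, pw)
  num <- s_rm[ii, jj] - s_r[ii, jj] * s_m[ii, jj] / n_ov[ii, jj]
  v_r <- s_r2[ii, jj] - s_r[ii, jj]^2 / n_ov[ii, jj]
  v_m <- s_m2[ii, jj] - s_m[ii, jj]^2 / n_ov[ii, jj]
  den <- sqrt(pmax(v_r, 0) * pmax(v_m, 0))
  ncc <- num / den
  ncc[den <= 1e-12 * max(den)] <- -Inf
  ncc[n_ov[ii, jj] < min_overlap_frac * h * w] <- -Inf
  ncc[!is.finite(ncc)] <- -Inf

  k <- arrayInd(which.max(ncc), dim(ncc))
  dy <- dys[k[1]]; dx <- dxs[k[2]]
  peak <- ncc[k[1], k[2]]
  if (!is.finite(peak))
    stop("no admissible shift found within max_shift_px")
  peak <- min(max(peak, -1), 1)

  shift <- c(dy = dy, dx = dx)
  if (subpixel) {
    refine <- function(i, vals) { # 1D parabolic peak interpolation
      if (i <= 1L || i >= length(vals) || !all(is.finite(vals[(i - 1):(i + 1)])))
        return(0)
      a <- vals[i - 1]; b <- vals[i]; c <- vals[i + 1]
      d <- a - 2 * b + c
      if (d >= 0) return(0)
      min(max((a - c) / (2 * d), -0.5), 0.5)
    }
    shift <- c(dy = dy + refine(k[1], ncc[, k[2]]),
               dx = dx + refine(k[2], ncc[k[1], ]))
  }
  list(shift = shift, peak_correlation = peak)
}

#' Correct tissue drift using the structural channel
#'
#' Recovers the slow rigid drift of the tissue from the structural (collagen
#' second-harmonic) channel and removes it from both channels. Each frame's
#' structural image is registered against the previous *aligned* frame (or
#' against frame 0 with `reference = "first"`); the per-step shifts accumulate
#' into a cumulative drift trace relative to frame 0, and both channels of
#' every frame are translated by the negated cumulative shift, zero-filling
#' exposed borders. The cell channel never enters the shift estimation.
#'
#' @param movie an [rt_movie()] with at least 2 frames.
#' @param max_shift_px maximum per-step shift searched (pixels). The default,
#'   50 px (about 27 um at the default calibration), accommodates drift of the
#'   same order as cell displacement.
#' @param reference `"previous"` (default) registers each frame against the
#'   previous aligned frame; `"first"` registers everything against frame 0.
#' @param min_correlation if the peak correlation of any step falls below this
#'   value a warning naming the frame is emitted (registration still proceeds).
#' @param subpixel passed to [estimate_shift()]; fractional shifts are rounded
#'   to integers before frames are translated but reported unrounded in the
#'   trace.
#' @return list with `movie` (the aligned [rt_movie()]) and `drift` (a
#'   data.frame with columns `frame` (0-based), `dy_px`, `dx_px` cumulative
#'   shift relative to frame 0, and `peak_corr`).
#' @export
correct_drift <- function(movie, max_shift_px = 50,
                          reference = c("previous", "first"),
                          min_correlation = 0, subpixel = FALSE) {
  stopifnot(inherits(movie, "rt_movie"))
  reference <- match.arg(reference)
  nf <- n_frames(movie)
  if (nf < 2L) stop("drift correction needs at least 2 frames")

  cum <- matrix(0, nf, 2)      # cumulative (dy, dx) per frame
  peak <- rep(NA_real_, nf); peak[1] <- 1
  ref_img <- movie$structural[[1]]

  for (t in 2:nf) {
    # pre-align frame t by the previous cumulative shift, then estimate the
    # residual step against the reference image
    prev <- round(cum[t - 1, ])
    moved <- translate_int(movie$structural[[t]], -prev[1], -prev[2])
    est <- tryCatch(
      estimate_shift(ref_img, moved, max_shift_px, subpixel = subpixel),
      error = function(e)
        stop(sprintf("registration failed at frame %d: %s", t - 1,
                     conditionMessage(e)), call. = FALSE))
    cum[t, ] <- prev + est$shift
    peak[t] <- est$peak_correlation
    if (est$peak_correlation < min_correlation)
      warning(sprintf("frame %d: peak correlation %.3f below %.3f",
                      t - 1, est$peak_correlation, min_correlation))
    if (reference == "previous")
      ref_img <- translate_int(movie$structural[[t]],
                               -round(cum[t, 1]), -round(cum[t, 2]))
  }

  aligned_cell <- vector("list", nf)
  aligned_shg <- vector("list", nf)
  for (t in seq_len(nf)) {
    s <- round(cum[t, ])
    aligned_cell[[t]] <- translate_int(movie$cell[[t]], -s[1], -s[2])
    aligned_shg[[t]] <- translate_int(movie$structural[[t]], -s[1], -s[2])
  }
  out <- rt_movie(aligned_cell, aligned_shg, movie$pixel_size_um,
                  movie$frame_interval_min)
  drift <- data.frame(frame = seq_len(nf) - 1L,
                      dy_px = cum[, 1], dx_px = cum[, 2], peak_corr = peak)
  list(movie = out, drift = drift)
}
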