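#' Histogram of Mean Roundness Coefficients
#'
#' Bins MRC values into fixed-width bins spanning \[0, 1\]. Bins are
#' left-open/right-closed `(a, b]` except the first, which is closed on both
#' sides, so a value exactly on an interior edge falls in the lower bin and
#' every value in \[0, 1\] is counted exactly once.
#'
#' @param mrc_values numeric vector of MRC values in \[0, 1\].
#' @param bin_width bin width (default 0.05, i.e. 20 bins over \[0, 1\]).
#' @return list with `bin_edges` (length `n_bins + 1`), `bin_counts`
#'   (integer, sums to `length(mrc_values)`) and `bin_mids`.
#' @export
build_mrc_histogram <- function(mrc_values, bin_width = 0.05) {
  if (length(mrc_values) == 0L) stop("no MRC values to bin")
  if (!(bin_width > 0)) stop("bin_width must be positive")
  if (any(mrc_values < 0 | mrc_values > 1))
    stop("MRC values must lie in [0, 1]")
  n_bins <- ceiling(1 / bin_width - 1e-9)
  edges <- c(seq(0, by = bin_width, length.out = n_bins), 1)
  counts <- as.integer(table(cut(mrc_values, breaks = edges,
                                 include.lowest = TRUE, right = TRUE)))
  list(bin_edges = edges, bin_counts = counts,
       bin_mids = (edges[-1] + edges[-length(edges)]) / 2)
}

# Count local maxima of a lightly smoothed count vector (3-point moving
# average); used to verify bimodality before attempting the mixture fit.
count_modes <- function(counts) {
  n <- length(counts)
  if (n < 3L) return(as.integer(n > 0 && max(counts) > 0))
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(counts[1:2]); sm[n] <- mean(counts[(n - 1):n])
  sm <- as.numeric(sm)
  modes <- 0L
  i <- 2L
  while (i <= n - 1L) {
    if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]) {
      # skip plateau
      j <- i
      while (j < n && sm[j + 1] == sm[i]) j <- j + 1L
      if (j == n || sm[j + 1] < sm[i]) modes <- modes + 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  modes
}

#' Fit a sum of two Gaussians to an MRC histogram
#'
#' Nonlinear least squares of
#' `a1 * exp(-(x - mu1)^2 / (2 s1^2)) + a2 * exp(-(x - mu2)^2 / (2 s2^2))`
#' against the bin-centre counts (Levenberg-Marquardt). Initialization is
#' deterministic: component means at the two most separated histogram peaks,
#' sigmas at a quarter of the peak separation, amplitudes at the peak heights.
#' The fit
#' errors out — rather than returning a silent threshold — if the histogram
#' does not show two modes after light smoothing, or if the optimizer fails.
#'
#' @param bin_edges,bin_counts histogram as from [build_mrc_histogram()].
#' @return an object of class `rt_mixture_fit`: list with `amplitudes`,
#'   `means` (sorted, `means[1] < means[2]`), `sigmas`, `threshold` (the local
#'   minimum of the fitted curve between the means, see [find_threshold()]),
#'   `r_squared` (1 - SS_res / SS_tot against the bin counts), `bin_edges`,
#'   `bin_counts`, and `empirical_dip` (the lowest-count bin centre between the
#'   two initial peaks, reported as a diagnostic).
#' @export
fit_double_gaussian <- function(bin_edges, bin_counts) {
  stopifnot(length(bin_edges) == length(bin_counts) + 1,
            all(diff(bin_edges) > 0), all(bin_counts >= 0))
  if (sum(bin_counts > 0) < 8L)
    stop("too few nonzero bins (need >= 8) for a two-component fit")
  if (count_modes(bin_counts) < 2L)
    stop("histogram is unimodal: no two-component structure to fit")
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  y <- as.numeric(bin_counts)

  # deterministic initialization from the two most separated local peaks
  n <- length(y)
  peak_idx <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > 0 && y[i] >= l && y[i] >= r
  }, logical(1)))
  # keep substantial peaks only (>= 10% of the tallest), then take the most
  # separated pair among the four tallest
  peak_idx <- peak_idx[y[peak_idx] >= 0.1 * max(y[peak_idx])]
  peak_idx <- peak_idx[order(-y[peak_idx])]
  if (length(peak_idx) < 2L)
    stop("histogram is unimodal: no two-component structure to fit")
  top <- peak_idx[seq_len(min(4L, length(peak_idx)))]
  combs <- utils::combn(top, 2)
  sep <- abs(mids[combs[1, ]] - mids[combs[2, ]])
  pair <- sort(combs[, which.max(sep)])
  mu0 <- mids[pair]
  a0 <- pmax(y[pair], 1)
  s0 <- rep(max(abs(diff(mu0)) / 4, diff(bin_edges)[1]), 2)

  model <- function(p, x)
    p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) +
    p[4] * exp(-(x - p[5])^2 / (2 * p[6]^2))
  fit <- minpack.lm::nls.lm(
    par = c(a0[1], mu0[1], s0[1], a0[2], mu0[2], s0[2]),
    fn = function(p) y - model(p, mids),
    lower = c(0, 0, 1e-4, 0, 0, 1e-4),
    upper = c(Inf, 1, 1, Inf, 1, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:4))
    stop("double-Gaussian fit did not converge: ", fit$message, call. = FALSE)
  p <- fit$par
  ord <- order(c(p[2], p[5]))
  means <- c(p[2], p[5])[ord]
  sigmas <- c(p[3], p[6])[ord]
  amps <- c(p[1], p[4])[ord]
  if (any(amps <= 0) || means[1] == means[2])
    stop("double-Gaussian fit degenerate: components collapsed")

  yhat <- model(p, mids)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

  between <- which(mids > min(mu0) & mids < max(mu0))
  dip <- if (length(between) > 0) mids[between[which.min(y[between])]]
  else NA_real_

  out <- structure(list(amplitudes = amps, means = means, sigmas = sigmas,
                        threshold = NA_real_, r_squared = r2,
                        bin_edges = bin_edges, bin_counts = bin_counts,
                        empirical_dip = dip),
                   class = "rt_mixture_fit")
  out$threshold <- find_threshold(out)
  out
}

#' @export
print.rt_mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-Gaussian MRC fit: means %.3f / %.3f, ",
                     "sigmas %.3f / %.3f\n  threshold %.3f, R^2 = %.3f\n"),
              x$means[1], x$means[2], x$sigmas[1], x$sigmas[2],
              x$threshold, x$r_squared))
  invisible(x)
}

#' Evaluate a fitted two-Gaussian curve
#'
#' @param fit an `rt_mixture_fit`.
#' @param x points at which to evaluate.
#' @return fitted counts at `x`.
#' @export
mixture_curve <- function(fit, x) {
  fit$amplitudes[1] * exp(-(x - fit$means[1])^2 / (2 * fit$sigmas[1]^2)) +
    fit$amplitudes[2] * exp(-(x - fit$means[2])^2 / (2 * fit$sigmas[2]^2))
}

#' Classification threshold from a two-Gaussian fit
#'
#' Locates the local minimum of the fitted curve strictly between the two
#' component means — the natural split point of a bimodal roundness
#' distribution — on a fine grid followed by golden-section refinement.
#' Overlapping components with no interior minimum raise an error.
#'
#' @param fit an `rt_mixture_fit` (means sorted ascending).
#' @return the threshold, a value in `(means[1], means[2])`.
#' @export
find_threshold <- function(fit) {
  stopifnot(inherits(fit, "rt_mixture_fit"))
  m1 <- fit$means[1]; m2 <- fit$means[2]
  if (!(m1 < m2)) stop("component means must be distinct")
  grid <- seq(m1, m2, length.out = 2001)
  vals <- mixture_curve(fit, grid)
  k <- which.min(vals)
  if (k == 1L || k == length(grid))
    stop("no interior minimum between the component means: ",
         "components overlap too strongly for a threshold")
  opt <- stats::optimize(function(x) mixture_curve(fit, x),
                         interval = c(grid[k - 1], grid[k + 1]))
  th <- opt$minimum
  if (mixture_curve(fit, th) > min(mixture_curve(fit, c(m1, m2))))
    stop("fitted curve has no valley below both modes")
  th
}

#' Label tracks as dendritic-shaped or round-shaped
#'
#' Applies the MRC threshold: tracks with `mrc < threshold` are
#' Dendritic-shaped Cells (`"DSC"`), tracks with `mrc >= threshold` are
#' Round-shaped Cells (`"RSC"`; a value exactly at the threshold is assigned
#' to the round class, the documented tie rule).
#'
#' @param metrics data.frame with `track_id` and `mrc` columns (from
#'   [track_metrics()]).
#' @param threshold MRC threshold in (0, 1); e.g. the fitted
#'   [find_threshold()] value, or the fixed operating value 0.35.
#' @return list with `labels` (data.frame `track_id`, `mrc`, `label`) and
#'   `fractions` (named numeric, proportions of DSC and RSC).
#' @export
classify_tracks <- function(metrics, threshold) {
  stopifnot(is.data.frame(metrics),
            all(c("track_id", "mrc") %in% names(metrics)),
            threshold > 0, threshold < 1)
  label <- ifelse(metrics$mrc < threshold, "DSC", "RSC")
  labels <- data.frame(track_id = metrics$track_id, mrc = metrics$mrc,
                       label = label)
  fr <- c(DSC = mean(label == "DSC"), RSC = mean(label == "RSC"))
  list(labels = labels, fractions = fr, threshold = threshold)
}
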