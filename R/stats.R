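#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null distribution
#' is enumerated when the smaller sample has at most 8 values and there are no
#' ties; otherwise the tie-corrected normal approximation (with continuity
#' correction) is used.
#'
#' @param sample_a,sample_b numeric vectors, both nonempty.
#' @return list with `u_statistic` (the U of `sample_a`, in
#'   `[0, n_a * n_b]`), `p_value` (two-sided), `n_a`, `n_b`, `exact` (logical:
#'   was the exact distribution used?).
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (length(sample_a) < 1 || length(sample_b) < 1)
    stop("both samples must contain at least one value")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- min(length(sample_a), length(sample_b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(u_statistic = unname(wt$statistic),
       p_value = min(unname(wt$p.value), 1),
       n_a = length(sample_a), n_b = length(sample_b), exact = exact)
}

#' Significance stars for a p-value
#'
#' Maps a p-value to the star convention used in the figures:
#' `***` for p < 0.0001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#' Note the three-star cut at 0.0001, not the more common 0.001.
#'
#' @param p p-value in (0, 1\].
#' @return one of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
significance_stars <- function(p) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (p < 0.0001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare motility metrics between groups
#'
#' Pools tracks per group and runs a Mann-Whitney test for every requested
#' metric and group contrast, attaching significance stars. Each track is one
#' statistical unit (one value per cell). A Holm-adjusted p-value column is
#' included alongside the unadjusted values for transparency; the stars follow
#' the unadjusted p-values, matching the single-test-at-a-time convention of
#' the figures.
#'
#' @param metrics data.frame with one row per track, containing the metric
#'   columns and the grouping column.
#' @param group_col name of the grouping column in `metrics`.
#' @param metric_cols character vector of metric column names to compare
#'   (default velocity, maximal distance, meandering index).
#' @param contrasts optional list of length-2 character vectors naming the
#'   group pairs to compare; default: all unordered pairs of observed groups.
#' @return data.frame with one row per (metric, contrast): `metric`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `u_statistic`, `p_value`,
#'   `p_holm`, `stars`. Contrasts with an empty group are skipped with a
#'   warning.
#' @export
compare_groups <- function(metrics, group_col,
                           metric_cols = c("velocity_um_min", "md_um", "mi"),
                           contrasts = NULL) {
  stopifnot(is.data.frame(metrics), group_col %in% names(metrics),
            all(metric_cols %in% names(metrics)))
  groups <- metrics[[group_col]]
  if (is.null(contrasts)) {
    lv <- sort(unique(as.character(groups)))
    if (length(lv) < 2) stop("need at least two groups to compare")
    cb <- utils::combn(lv, 2)
    contrasts <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  rows <- list()
  for (m in metric_cols) {
    for (ct in contrasts) {
      a <- metrics[[m]][groups == ct[1]]
      b <- metrics[[m]][groups == ct[2]]
      if (length(a) == 0 || length(b) == 0) {
        warning(sprintf("contrast %s vs %s skipped for %s: empty group",
                        ct[1], ct[2], m))
        next
      }
      mw <- mann_whitney(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group_a = ct[1], group_b = ct[2],
        n_a = mw$n_a, n_b = mw$n_b, u_statistic = mw$u_statistic,
        p_value = mw$p_value, stars = significance_stars(mw$p_value))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(metric = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0),
                      n_b = integer(0), u_statistic = numeric(0),
                      p_value = numeric(0), p_holm = numeric(0),
                      stars = character(0)))
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out <- out[, c("metric", "group_a", "group_b", "n_a", "n_b",
                 "u_statistic", "p_value", "p_holm", "stars")]
  rownames(out) <- NULL
  out
}
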