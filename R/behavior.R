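#' Courtship index from per-frame courting indicators
#'
#' The courtship index (CI) is the fraction of the scoring window a male
#' spends courting. Recordings last 12.5 minutes and scoring starts at
#' t = 2.5 minutes, so the default window is `[2.5, 12.5)` min (half-open;
#' frames belong to the window by their start time).
#'
#' @param record data frame with columns `frame_time_s` (frame start time
#'   in seconds) and `courting` (0/1 or logical).
#' @param window_start,window_end scoring window in minutes.
#' @return CI in `[0, 1]`.
#' @export
courtship_index <- function(record, window_start = 2.5, window_end = 12.5) {
  if (window_end <= window_start)
    stop_axonloc("window_end must exceed window_start")
  t <- record$frame_time_s
  if (!length(t)) stop_axonloc("empty recording")
  dt <- if (length(t) > 1L) stats::median(diff(sort(t))) else 0
  if (min(t) > window_start * 60 || max(t) + dt < window_end * 60)
    stop_axonloc(sprintf(
      "recording [%.1f, %.1f] s does not cover the scoring window [%.0f, %.0f] s",
      min(t), max(t), window_start * 60, window_end * 60))
  in_win <- t >= window_start * 60 & t < window_end * 60
  mean(as.logical(record$courting[in_win]))
}

#' Memory (courtship suppression) index
#'
#' `MI = 1 - CI_trained / mean(CI_naive)`: 1 for a fully suppressing
#' trained male (CI 0), 0 when the trained male courts as much as the naive
#' reference, and negative when it courts more. The index is not clipped.
#'
#' @param ci_trained courtship index (or vector of indices) of trained
#'   males.
#' @param naive_cis courtship indices of the naive reference group; their
#'   mean must be positive.
#' @return Numeric vector of memory indices (`MI <= 1`).
#' @export
memory_index <- function(ci_trained, naive_cis) {
  m <- mean(naive_cis)
  if (!is.finite(m) || m <= 0)
    stop_axonloc("mean naive courtship index must be positive")
  1 - ci_trained / m
}

#' Compare memory indices between groups
#'
#' Thin wrapper around standard two-sample tests for reporting: unpaired
#' two-tailed t-test or Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param x,y numeric vectors (e.g. memory indices of two genotypes).
#' @param method `"t"` or `"wilcox"`.
#' @return The `htest` object from [stats::t.test()] or
#'   [stats::wilcox.test()].
#' @export
compare_groups <- function(x, y, method = c("t", "wilcox")) {
  method <- match.arg(method)
  if (method == "t") stats::t.test(x, y) else stats::wilcox.test(x, y)
}
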