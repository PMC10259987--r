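#' Max-min ramp slope of a trace segment
#'
#' Slope of the line connecting the maximum and the minimum of the segment:
#' `(s[argmax] - s[argmin]) / (t[argmax] - t[argmin])`. Positive when the
#' maximum occurs after the minimum (a ramp up). First occurrences win ties;
#' a constant segment has slope 0 by definition.
#'
#' @param values segment values (typically the 0.5 s ending at food-port
#'   entry).
#' @param times sample times, seconds.
#' @return Slope in signal units per second.
#' @export
maxmin_slope <- function(values, times) {
  if (length(values) < 2L) stopf("maxmin_slope needs at least 2 samples")
  if (length(values) != length(times)) stopf("values/times length mismatch")
  imax <- which.max(values)
  imin <- which.min(values)
  if (imax == imin) return(0)
  (values[imax] - values[imin]) / (times[imax] - times[imin])
}

#' Peak of a post-event segment
#'
#' Maximum of the segment (e.g. within 1 s after a hopper click). No
#' rectification: an all-negative segment returns its (negative) maximum.
#'
#' @param values segment values.
#' @return The maximum.
#' @export
peak_statistic <- function(values) {
  if (!length(values)) stopf("empty segment")
  max(values)
}

# Vectorized statistic over the rows of a window matrix (uniform dt).
# First-occurrence argmax/argmin matches maxmin_slope exactly.
.stat_rows <- function(M, dt, statistic) {
  if (statistic == "peak") return(apply(M, 1L, max))
  jmax <- max.col(M, ties.method = "first")
  jmin <- max.col(-M, ties.method = "first")
  n <- nrow(M)
  vmax <- M[cbind(seq_len(n), jmax)]
  vmin <- M[cbind(seq_len(n), jmin)]
  out <- (vmax - vmin) / ((jmax - jmin) * dt)
  out[jmax == jmin] <- 0
  out
}

# Extract per-event window rows from a trace. Slope windows end at the event
# ([-w, 0)); peak windows start at it ([0, +w)).
.event_windows <- function(trace, event_times, nw, statistic) {
  rate <- trace$rate
  i0 <- round((event_times - trace$times[1]) * rate) + 1L
  if (statistic == "maxmin_slope") { lo <- i0 - nw; hi <- i0 - 1L }
  else { lo <- i0; hi <- i0 + nw - 1L }
  ok <- lo >= 1L & hi <= length(trace$values)
  idx <- outer(lo[ok], seq_len(nw) - 1L, "+")
  list(M = matrix(trace$values[idx], nrow = sum(ok)), ok = ok)
}

#' Shuffle-null test of an event-aligned statistic
#'
#' Compares the mean of a statistic over real events against a null built
#' from random time points: the observed value is the mean over real events
#' of either the max-min slope in the `window` seconds before each event, or
#' the peak in the `window` seconds after it. Each of `n_shuffles` shuffles
#' draws the same number of pseudo-event times uniformly from the session
#' (with window-sized margins at both ends) and recomputes the mean. The 95%
#' chance range is the (2.5th, 97.5th) percentile of the null; the result is
#' significant when the observed mean lies outside it (two-sided; the
#' direction is reported separately as the sign of the observed value).
#'
#' @param trace a [photo_trace()] (dF/F or firing rate; the statistic is
#'   unit-agnostic).
#' @param event_times numeric vector of event times, seconds.
#' @param statistic `"maxmin_slope"` or `"peak"`.
#' @param window window length, seconds (default 0.5 for the slope, 1.0 for
#'   the peak, matching the analysis conventions).
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed optional integer seed for the shuffle draws.
#' @param per_event_null if `TRUE`, the null values are per-pseudo-event
#'   statistics rather than means over matched pseudo-event sets.
#' @return Object of class `shuffle_test_result`: `statistic_name`,
#'   `observed`, `null_values`, `ci`, `significant`, `direction`,
#'   `n_events`, `n_shuffles`, `seed`.
#' @export
shuffle_test <- function(trace, event_times,
                         statistic = c("maxmin_slope", "peak"),
                         window = NULL, n_shuffles = 1000, seed = NULL,
                         per_event_null = FALSE) {
  stopifnot(inherits(trace, "photo_trace"))
  statistic <- match.arg(statistic)
  if (is.null(window)) window <- if (statistic == "maxmin_slope") 0.5 else 1.0
  check_positive(window, "window")
  if (n_shuffles < 100) warning("fewer than 100 shuffles; the 95% range will be unstable")
  t1 <- trace$times[1]; t2 <- trace$times[length(trace$times)]
  if ((t2 - t1) < 10 * window)
    stopf("session (%.3g s) shorter than 10 windows (%.3g s)", t2 - t1, 10 * window)
  nw <- round(window * trace$rate)
  if (nw < 2L) stopf("window too short for the trace's sampling rate")
  dt <- 1 / trace$rate

  ew <- .event_windows(trace, event_times, nw, statistic)
  if (!nrow(ew$M)) stopf("no event window fits inside the trace")
  observed <- mean(.stat_rows(ew$M, dt, statistic))
  n_ev <- nrow(ew$M)

  null_values <- with_seed(seed, {
    lo_t <- t1 + window
    hi_t <- t2 - window
    pseudo <- runif(n_shuffles * n_ev, lo_t, hi_t)
    pw <- .event_windows(trace, pseudo, nw, statistic)
    stats <- .stat_rows(pw$M, dt, statistic)
    if (per_event_null) stats
    else colMeans(matrix(stats, nrow = n_ev))
  })
  ci <- unname(quantile(null_values, c(0.025, 0.975)))
  significant <- observed < ci[1] || observed > ci[2]
  structure(list(statistic_name = statistic, observed = observed,
                 null_values = null_values, ci = ci,
                 significant = significant,
                 direction = sign(observed), n_events = n_ev,
                 n_shuffles = n_shuffles, seed = seed, window = window),
            class = "shuffle_test_result")
}

#' @export
print.shuffle_test_result <- function(x, ...) {
  cat(sprintf("<shuffle_test> %s: observed %.4g, 95%% chance range [%.4g, %.4g] (%d shuffles, %d events)\n",
              x$statistic_name, x$observed, x$ci[1], x$ci[2],
              x$n_shuffles, x$n_events))
  cat(sprintf("  %s (direction %s)\n",
              if (x$significant) "SIGNIFICANT (outside the chance range)" else "not significant",
              c("-", "0", "+")[x$direction + 2]))
  invisible(x)
}

#' @export
plot.shuffle_test_result <- function(x, ...) {
  graphics::hist(x$null_values, breaks = 40, main = x$statistic_name,
                 xlab = "null statistic", ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  graphics::abline(v = x$ci, lty = 2)
  invisible(x)
}

#' Tally significant shuffle-test results across recordings
#'
#' @param results named list of [shuffle_test()] results (one per recording /
#'   fiber placement).
#' @return Object of class `significance_tally`: `k` significant out of `n`,
#'   plus a per-recording table with the direction of each observed
#'   statistic (so "ramped down" recordings are distinguishable).
#' @export
count_significant <- function(results) {
  if (!length(results)) stopf("empty result set")
  stopifnot(all(vapply(results, inherits, logical(1), "shuffle_test_result")))
  ids <- names(results)
  if (is.null(ids)) ids <- as.character(seq_along(results))
  tab <- data.frame(
    recording_id = ids,
    statistic = vapply(results, function(r) r$statistic_name, ""),
    observed = vapply(results, function(r) r$observed, 0),
    ci_lo = vapply(results, function(r) r$ci[1], 0),
    ci_hi = vapply(results, function(r) r$ci[2], 0),
    significant = vapply(results, function(r) r$significant, FALSE),
    direction = vapply(results, function(r) r$direction, 0),
    stringsAsFactors = FALSE)
  structure(list(k = sum(tab$significant), n = nrow(tab), table = tab),
            class = "significance_tally")
}

#' @export
print.significance_tally <- function(x, ...) {
  up <- sum(x$table$significant & x$table$direction > 0)
  dn <- sum(x$table$significant & x$table$direction < 0)
  cat(sprintf("<significance_tally> %d/%d significant (%d up, %d down)\n",
              x$k, x$n, up, dn))
  invisible(x)
}
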