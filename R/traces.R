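#' Uniformly sampled signal trace
#'
#' Light container for a uniformly sampled time series: a demultiplexed
#' fluorescence channel, an isosbestic-corrected dF/F trace, or a smoothed
#' firing-rate estimate. All alignment and shuffle-test machinery operates on
#' this class regardless of units.
#'
#' @param times numeric vector of sample times (seconds), strictly increasing
#'   and uniformly spaced.
#' @param values numeric vector, same length as `times`.
#' @param units character label for the values axis (e.g. `"dF/F"`, `"Hz"`,
#'   `"V"`).
#' @param label channel / unit label.
#' @param zscored logical; has the trace been z-scored?
#' @param fit_coeffs optional named numeric `(slope, intercept)` of the
#'   isosbestic least-squares fit that produced a corrected trace.
#' @return An object of class `photo_trace` with elements `times`, `values`,
#'   `rate` (Hz), `units`, `label`, `zscored` and optionally `fit_coeffs`.
#' @export
photo_trace <- function(times, values, units = "a.u.", label = "trace",
                        zscored = FALSE, fit_coeffs = NULL) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stopf("times (%d) and values (%d) differ in length", length(times), length(values))
  if (length(times) < 2L) stopf("a trace needs at least 2 samples")
  dt <- diff(times)
  if (any(dt <= 0)) stopf("trace times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stopf("trace times must be uniformly spaced")
  structure(
    list(times = times, values = values, rate = 1 / mean(dt),
         units = units, label = label, zscored = isTRUE(zscored),
         fit_coeffs = fit_coeffs),
    class = "photo_trace")
}

#' @export
print.photo_trace <- function(x, ...) {
  cat(sprintf("<photo_trace> %s: %d samples @ %.4g Hz, t = [%.3f, %.3f] s (%s)%s\n",
              x$label, length(x$values), x$rate, x$times[1],
              x$times[length(x$times)], x$units,
              if (x$zscored) ", z-scored" else ""))
  if (!is.null(x$fit_coeffs))
    cat(sprintf("  isosbestic fit: slope %.4g, intercept %.4g\n",
                x$fit_coeffs[["slope"]], x$fit_coeffs[["intercept"]]))
  invisible(x)
}

#' @export
plot.photo_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = x$units, main = x$label, ...)
  invisible(x)
}

#' @export
as.data.frame.photo_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' Raw multiplexed photometry stream
#'
#' A single femtowatt-detector sample stream in which successive LED frames
#' interleave the excitation channels (time-division multiplexing).
#'
#' @param samples numeric detector samples (volts or arbitrary units).
#' @param sample_rate sampling rate in Hz (default 10000).
#' @param t0 time of the first sample, seconds.
#' @return Object of class `raw_photometry`.
#' @export
raw_photometry <- function(samples, sample_rate = 10000, t0 = 0) {
  check_positive(sample_rate, "sample_rate")
  if (length(samples) < 1L) stopf("empty detector stream")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t0 = t0),
            class = "raw_photometry")
}

#' @export
print.raw_photometry <- function(x, ...) {
  cat(sprintf("<raw_photometry> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Behavioral / stimulation event log
#'
#' Typed, timestamped events for one session. Recognised event types are
#' `light_on`, `center_in`, `go_cue`, `choice_in`, `click`, `food_port_in`,
#' `laser_pulse`, `timeout`.
#'
#' @param time_s event times, seconds from session start (non-decreasing).
#' @param event_type character vector of event types.
#' @param trial_id integer trial identifiers.
#' @param condition condition / treatment label.
#' @param extra free-form annotation column.
#' @return A `data.frame` of class `event_log` with columns
#'   `time_s,event_type,trial_id,condition,extra`.
#' @export
event_log <- function(time_s, event_type, trial_id = NA_integer_,
                      condition = "none", extra = "") {
  if (!length(time_s)) {
    trial_id <- integer(0); condition <- character(0); extra <- character(0)
    event_type <- character(0)
  }
  df <- data.frame(time_s = as.numeric(time_s),
                   event_type = as.character(event_type),
                   trial_id = as.integer(trial_id),
                   condition = as.character(condition),
                   extra = as.character(extra),
                   stringsAsFactors = FALSE)
  if (nrow(df) && is.unsorted(df$time_s)) stopf("event times must be non-decreasing")
  known <- c("light_on", "center_in", "go_cue", "choice_in", "click",
             "food_port_in", "laser_pulse", "timeout", "session_start",
             "session_end")
  bad <- setdiff(unique(df$event_type), known)
  if (length(bad)) warning("unrecognised event types: ", paste(bad, collapse = ", "))
  class(df) <- c("event_log", "data.frame")
  df
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d events", nrow(x)))
  if (nrow(x)) {
    tab <- table(x$event_type)
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Times of all events of one type
#'
#' @param events an [event_log()].
#' @param type event type label.
#' @return Numeric vector of event times (seconds).
#' @export
event_times <- function(events, type) events$time_s[events$event_type == type]
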