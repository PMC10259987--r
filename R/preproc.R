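#' LED multiplexing schedule
#'
#' Time-division multiplexing schedule: LEDs are switched on and off in fixed
#' frames (default 10 ms frames, 4 ms on / 6 ms off), cycling through the
#' channels frame by frame. The dual-color configuration
#' (565 / 470 / 405 nm) and the optogenetics configuration (565 / 405 nm) are
#' the same schedule with a different channel list.
#'
#' @param frame_len frame length, seconds (default 0.010).
#' @param on_len LED on-time within a frame, seconds (default 0.004).
#' @param channels data.frame with columns `label`, `wavelength_nm`,
#'   `isosbestic` (logical), in excitation order. Default: 565 nm signal +
#'   405 nm isosbestic control.
#' @return Object of class `led_schedule`.
#' @export
led_schedule <- function(frame_len = 0.010, on_len = 0.004,
                         channels = data.frame(
                           label = c("green_565", "violet_405"),
                           wavelength_nm = c(565, 405),
                           isosbestic = c(FALSE, TRUE))) {
  check_positive(frame_len, "frame_len")
  check_positive(on_len, "on_len")
  if (on_len >= frame_len) stopf("on_len must be shorter than frame_len")
  if (!is.data.frame(channels) ||
      !all(c("label", "wavelength_nm", "isosbestic") %in% names(channels)) ||
      nrow(channels) < 1L)
    stopf("channels must be a data.frame with label, wavelength_nm, isosbestic")
  structure(list(frame_len = frame_len, on_len = on_len, channels = channels),
            class = "led_schedule")
}

#' @export
print.led_schedule <- function(x, ...) {
  cat(sprintf("<led_schedule> %g ms frames (%g ms on), %d channels: %s\n",
              x$frame_len * 1000, x$on_len * 1000, nrow(x$channels),
              paste(x$channels$label, collapse = ", ")))
  invisible(x)
}

#' Demultiplex a raw detector stream into per-channel traces
#'
#' The single detector stream interleaves excitation channels frame by frame.
#' Each frame's value is the mean of the detector samples inside that frame's
#' LED on-window, after discarding the first `settle_ms` of the window
#' (LED/detector settling). Frames are timestamped at the on-window center.
#' A trailing partial channel cycle is dropped, so every returned trace has
#' the same length and a uniform rate of `1 / (frame_len * n_channels)` Hz.
#'
#' @param raw a [raw_photometry()] stream.
#' @param schedule the [led_schedule()] used during acquisition.
#' @param settle_ms settling time discarded at each on-window start,
#'   milliseconds (default 1).
#' @return List of [photo_trace()] objects, one per scheduled channel, named
#'   by channel label.
#' @export
demultiplex <- function(raw, schedule, settle_ms = 1) {
  stopifnot(inherits(raw, "raw_photometry"), inherits(schedule, "led_schedule"))
  fs <- raw$sample_rate
  spf_real <- fs * schedule$frame_len
  spf <- round(spf_real)
  if (abs(spf_real - spf) > 1e-6 || spf < 1)
    stopf("sample_rate (%g Hz) is not commensurate with frame_len (%g s)",
          fs, schedule$frame_len)
  on_n <- round(fs * schedule$on_len)
  settle_n <- round(fs * settle_ms / 1000)
  if (settle_n >= on_n)
    stopf("settle_ms leaves no samples inside the on-window")
  nch <- nrow(schedule$channels)
  n <- length(raw$samples)
  if (n < 1L) stopf("empty detector stream")
  n_frames <- floor(n / spf)
  n_cycles <- floor(n_frames / nch)
  if (n_cycles < 1L)
    stopf("stream shorter than one full channel cycle (%d frames needed)", nch)
  n_frames <- n_cycles * nch
  fstart <- (seq_len(n_frames) - 1L) * spf        # 0-based sample offsets
  ch_of_frame <- ((seq_len(n_frames) - 1L) %% nch) + 1L
  win <- (settle_n + 1L):on_n                     # samples used within on-window
  out <- vector("list", nch)
  for (c in seq_len(nch)) {
    fs_c <- fstart[ch_of_frame == c]
    idx <- outer(win, fs_c, "+")                  # (win x frames)
    vals <- colMeans(matrix(raw$samples[idx], nrow = length(win)))
    times <- raw$t0 + fs_c / fs + schedule$on_len / 2
    out[[c]] <- photo_trace(times, vals, units = "F",
                            label = schedule$channels$label[c])
  }
  names(out) <- schedule$channels$label
  out
}

#' Isosbestic motion correction by least-squares rescaling
#'
#' Fits the isosbestic control channel onto the signal channel by ordinary
#' least squares over the whole session (`fitted = a * control + b`) and
#' returns `dff = (signal - fitted) / fitted`. A multiplicative artifact
#' shared by both channels (motion, and slow bleaching common to both) is
#' absorbed by the fit; signal-specific fluorescence changes survive as dF/F.
#'
#' @param signal [photo_trace()] of the signal channel.
#' @param control [photo_trace()] of the isosbestic channel; same time grid.
#' @return A [photo_trace()] of class `corrected_trace` in dF/F units, with
#'   `fit_coeffs = c(slope, intercept)`.
#' @export
isosbestic_correct <- function(signal, control) {
  stopifnot(inherits(signal, "photo_trace"), inherits(control, "photo_trace"))
  if (length(signal$values) != length(control$values))
    stopf("signal and control traces are not on the same time grid")
  off <- control$times - signal$times
  # channels from one TDM acquisition are staggered by < 1 cycle; that is the
  # matching case. Anything else is a genuine grid mismatch.
  if (max(abs(off - off[1])) > 1e-9 || abs(off[1]) >= 1 / signal$rate)
    stopf("signal and control traces are not on the same time grid")
  if (var(control$values) <= 0)
    stopf("degenerate regressor: isosbestic control has zero variance")
  a <- cov(signal$values, control$values) / var(control$values)
  b <- mean(signal$values) - a * mean(control$values)
  fitted <- a * control$values + b
  if (any(fitted == 0))
    stopf("fitted control crosses zero; dF/F undefined")
  dff <- (signal$values - fitted) / fitted
  tr <- photo_trace(signal$times, dff, units = "dF/F",
                    label = paste0(signal$label, "_dff"),
                    fit_coeffs = c(slope = a, intercept = b))
  class(tr) <- c("corrected_trace", class(tr))
  tr
}

#' @importFrom stats cov
NULL

#' Z-score a trace
#'
#' `(x - mean) / SD`, with the mean and SD taken over the whole session or
#' over a stated baseline window.
#'
#' @param trace a [photo_trace()].
#' @param baseline_window optional `c(start, end)` seconds; statistics are
#'   computed from samples inside this window only.
#' @return The trace with z-scored values and `zscored = TRUE`.
#' @export
zscore_trace <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "photo_trace"))
  v <- trace$values
  if (is.null(baseline_window)) {
    base <- v
  } else {
    if (length(baseline_window) != 2L ||
        baseline_window[1] < trace$times[1] - 1e-9 ||
        baseline_window[2] > trace$times[length(trace$times)] + 1e-9)
      stopf("baseline_window outside the session")
    base <- v[trace$times >= baseline_window[1] & trace$times <= baseline_window[2]]
  }
  s <- sqrt(mean((base - mean(base))^2))   # population SD (ddof = 0)
  if (!is.finite(s) || s == 0) stopf("zero-variance trace cannot be z-scored")
  out <- trace
  out$values <- (v - mean(base)) / s
  out$units <- "z"
  out$zscored <- TRUE
  out
}

#' Normalize per-subject response amplitudes to a reference condition
#'
#' Each subject's amplitudes are divided by that subject's amplitude at the
#' reference condition before any cross-subject averaging (e.g. normalizing
#' dose-response amplitudes to the 64-pulse response, or train responses to
#' the single-pulse response of matching width and power).
#'
#' @param responses data.frame with columns `subject`, `condition`,
#'   `amplitude`.
#' @param reference the reference condition label; must be present (and
#'   positive) for every subject.
#' @return The data.frame with an added `normalized` column.
#' @export
normalize_to_reference <- function(responses, reference) {
  if (!all(c("subject", "condition", "amplitude") %in% names(responses)))
    stopf("responses must have columns subject, condition, amplitude")
  subjects <- unique(responses$subject)
  ref <- setNames(rep(NA_real_, length(subjects)), subjects)
  for (s in subjects) {
    r <- responses$amplitude[responses$subject == s &
                             responses$condition == reference]
    if (length(r) != 1L)
      stopf("subject '%s' lacks a unique reference condition '%s'", s, reference)
    if (!is.finite(r) || r <= 0)
      stopf("subject '%s' has non-positive reference amplitude (%g)", s, r)
    ref[[as.character(s)]] <- r
  }
  responses$normalized <- responses$amplitude / ref[as.character(responses$subject)]
  responses
}

#' @importFrom stats setNames
NULL
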