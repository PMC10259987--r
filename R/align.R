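#' Peri-event matrix
#'
#' Trial-structured matrix of trace samples aligned to an event type. Built by
#' [align_trace()]; rows are trials, columns are samples on the trace's own
#' grid (nearest-frame alignment, no resampling). Windows are half-open
#' `[-pre, +post)`: the event sample is the first post-event sample.
#'
#' @name peri_event_matrix
NULL

new_peri_event_matrix <- function(data, times_rel, alignment_event, window,
                                  trial_times, meta, rate, excluded) {
  structure(list(data = data, times_rel = times_rel,
                 alignment_event = alignment_event, window = window,
                 trial_times = trial_times, trial_meta = meta, rate = rate,
                 excluded = excluded),
            class = "peri_event_matrix")
}

#' @export
print.peri_event_matrix <- function(x, ...) {
  cat(sprintf("<peri_event_matrix> %d trials x %d samples, aligned to '%s', window [-%g, +%g) s @ %.4g Hz\n",
              nrow(x$data), ncol(x$data), x$alignment_event,
              x$window[1], x$window[2], x$rate))
  if (length(x$excluded))
    cat(sprintf("  %d event(s) excluded (window outside session): %s\n",
                length(x$excluded), paste(signif(x$excluded, 4), collapse = ", ")))
  invisible(x)
}

#' @export
plot.peri_event_matrix <- function(x, ...) {
  graphics::image(x$times_rel, seq_len(nrow(x$data)), t(x$data),
                  xlab = "time from event (s)", ylab = "trial",
                  main = x$alignment_event, ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Align a trace to behavioral events
#'
#' Extracts one row per event of `event_type`, sampled from the trace on its
#' own grid (nearest frame to the event time; no interpolation). Events whose
#' window would extend beyond the trace are excluded and reported in the
#' result's `excluded` field. Per-trial metadata records the behavioral
#' latency: time from the aligning event to the trial's `food_port_in` (or,
#' when aligning to `light_on`, to the trial's `center_in`).
#'
#' @param trace a [photo_trace()] (dF/F or firing rate).
#' @param events an [event_log()].
#' @param event_type event type to align to.
#' @param window `c(pre, post)` seconds; rows span `[-pre, +post)`.
#' @return A `peri_event_matrix`.
#' @export
align_trace <- function(trace, events, event_type, window = c(1, 1)) {
  stopifnot(inherits(trace, "photo_trace"))
  te <- events$time_s[events$event_type == event_type]
  tid <- events$trial_id[events$event_type == event_type]
  cond <- events$condition[events$event_type == event_type]
  if (!length(te)) stopf("no events of type '%s'; empty matrix", event_type)
  rate <- trace$rate
  npre <- round(window[1] * rate)
  npost <- round(window[2] * rate)
  if (npre + npost < 1L) stopf("window too short for the trace's rate")
  i0 <- round((te - trace$times[1]) * rate) + 1L   # first post-event sample
  lo <- i0 - npre
  hi <- i0 + npost - 1L
  ok <- lo >= 1L & hi <= length(trace$values)
  excluded <- te[!ok]
  if (!any(ok)) stopf("all events of type '%s' fall outside the trace", event_type)
  idx <- outer(lo[ok], seq_len(npre + npost) - 1L, "+")
  data <- matrix(trace$values[idx], nrow = sum(ok))
  times_rel <- (seq_len(npre + npost) - 1L - npre) / rate

  latency_to <- if (event_type == "light_on") "center_in" else "food_port_in"
  lat <- rep(NA_real_, sum(ok))
  kept_tid <- tid[ok]; kept_te <- te[ok]
  for (i in seq_along(kept_tid)) {
    cand <- events$time_s[events$event_type == latency_to &
                          events$trial_id == kept_tid[i] &
                          events$time_s >= kept_te[i]]
    if (length(cand)) lat[i] <- cand[1] - kept_te[i]
    else if (event_type == latency_to) lat[i] <- 0
  }
  meta <- data.frame(trial_id = kept_tid, latency = lat,
                     condition = cond[ok], stringsAsFactors = FALSE)
  new_peri_event_matrix(data, times_rel, event_type, window, kept_te, meta,
                        rate, excluded)
}

#' Sort peri-event trials by behavioral latency
#'
#' Rows (and metadata) are reordered by ascending latency with a stable sort,
#' so ties keep their original relative order.
#'
#' @param m a `peri_event_matrix` whose `trial_meta$latency` is complete.
#' @return The reordered matrix.
#' @export
sort_by_latency <- function(m) {
  stopifnot(inherits(m, "peri_event_matrix"))
  lat <- m$trial_meta$latency
  if (anyNA(lat))
    stopf("missing latencies for trial(s): %s",
          paste(m$trial_meta$trial_id[is.na(lat)], collapse = ", "))
  o <- order(lat)                      # radix: stable
  m$data <- m$data[o, , drop = FALSE]
  m$trial_meta <- m$trial_meta[o, , drop = FALSE]
  m$trial_times <- m$trial_times[o]
  m
}

#' Gaussian-kernel firing-rate estimate
#'
#' Convolves the spike train with a Gaussian kernel on a uniform grid. The
#' kernel weights are normalized so that the trapezoid-free quadrature
#' `sum(rate) * dt` equals the spike count exactly (spikes closer than the
#' kernel half-width to the grid edges lose the mass that falls outside).
#'
#' @param spikes a `spike_train` (or numeric vector of spike times).
#' @param kernel_sd Gaussian SD, seconds (default 0.1).
#' @param rate_grid output grid rate, Hz (default 100).
#' @param t_range `c(start, end)` of the output grid; defaults to `0` to the
#'   last spike (or 1 s for an empty train).
#' @return A [photo_trace()] in Hz.
#' @export
smooth_spikes <- function(spikes, kernel_sd = 0.1, rate_grid = 100,
                          t_range = NULL) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else as.numeric(spikes)
  check_positive(kernel_sd, "kernel_sd")
  check_positive(rate_grid, "rate_grid")
  if (is.null(t_range))
    t_range <- c(0, if (length(st)) max(st) + 5 * kernel_sd else 1)
  dt <- 1 / rate_grid
  grid <- seq(t_range[1], t_range[2], by = dt)
  if (!length(st)) {
    warning("empty spike train; returning a zero rate trace")
    return(photo_trace(grid, numeric(length(grid)), units = "Hz",
                       label = "rate"))
  }
  counts <- tabulate(pmin(pmax(floor((st - t_range[1]) / dt) + 1L, 1L),
                          length(grid)),
                     nbins = length(grid))
  half <- ceiling(6 * kernel_sd / dt)
  kern <- dnorm(seq(-half, half) * dt, sd = kernel_sd)
  kern <- kern / (sum(kern) * dt)       # unit mass per spike on the grid
  r <- stats::filter(c(numeric(half), counts, numeric(half)), kern, sides = 2)
  r <- as.numeric(r[(half + 1):(half + length(grid))])
  photo_trace(grid, r, units = "Hz",
              label = if (inherits(spikes, "spike_train")) spikes$unit_id else "rate")
}

#' Extract per-trial latencies between two event types
#'
#' Pairs events by `trial_id` and computes `t(to) - t(from)` per trial.
#' Trials whose `to` event is missing are marked censored. When
#' `min_latency` is given, rows with latency `<= min_latency` are dropped
#' (the long-latency convention; e.g. light-on to center-in more than 1 s
#' apart).
#'
#' @param events an [event_log()].
#' @param from_type,to_type event types delimiting the latency.
#' @param min_latency optional exclusion threshold, seconds.
#' @return A `latency_table` data.frame
#'   (`session_id,subject,condition,trial_id,latency_s,censored`).
#' @export
extract_latencies <- function(events, from_type, to_type, min_latency = NULL) {
  ef <- events[events$event_type == from_type, ]
  et <- events[events$event_type == to_type, ]
  if (!nrow(ef)) stopf("no events of type '%s'", from_type)
  rows <- lapply(seq_len(nrow(ef)), function(i) {
    tid <- ef$trial_id[i]
    cand <- et$time_s[et$trial_id == tid]
    if (!length(cand))
      return(data.frame(trial_id = tid, latency_s = NA_real_, censored = TRUE,
                        condition = ef$condition[i]))
    l <- cand[1] - ef$time_s[i]
    if (l < 0)
      stopf("data-integrity error: '%s' precedes '%s' in trial %s",
            to_type, from_type, tid)
    data.frame(trial_id = tid, latency_s = l, censored = FALSE,
               condition = ef$condition[i])
  })
  tab <- do.call(rbind, rows)
  if (!is.null(min_latency))
    tab <- tab[tab$censored | tab$latency_s > min_latency, , drop = FALSE]
  out <- data.frame(session_id = "session", subject = "S1",
                    condition = tab$condition, trial_id = tab$trial_id,
                    latency_s = tab$latency_s, censored = tab$censored,
                    stringsAsFactors = FALSE)
  class(out) <- c("latency_table", "data.frame")
  out
}
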