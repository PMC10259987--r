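#' Synthetic-session configuration
#'
#' All tunable parameters of the synthetic photometry / behavior generator.
#' The generator exists so that every downstream stage (demultiplexing,
#' isosbestic correction, alignment, shuffle statistics, plasticity and hazard
#' analyses) can be exercised against known ground truth.
#'
#' @param session_duration session length, seconds.
#' @param seed integer; together with the config it fully determines every
#'   generated sample and event.
#' @param sample_rate detector sampling rate, Hz.
#' @param bleach_tau photobleaching time constant, seconds. Bleaching is a
#'   single multiplicative exponential shared by all channels.
#' @param baseline_F baseline fluorescence level, arbitrary detector units.
#' @param motion_sd SD of the shared multiplicative motion artifact, as a
#'   fraction of baseline. The artifact is a low-pass (~2 Hz cutoff) Gaussian
#'   process injected identically into signal and isosbestic channels.
#' @param noise_sd per-sample detector noise SD, fraction of baseline.
#' @param transient_kernel named numeric `c(rise, decay, amp)`: rise and decay
#'   time constants (s) of the difference-of-exponentials transient evoked by
#'   a reward click (or a laser pulse), and its peak amplitude in dF/F units.
#'   The kernel is normalized to unit peak before scaling by `amp`.
#' @param ramp_slope slope of the approach ramp, dF/F per second.
#' @param ramp_duration ramp length, seconds; the ramp ends exactly at each
#'   food-port entry.
#' @param click_interval_range `c(min, max)` seconds; clicks occur at
#'   uniformly drawn intervals (default 15-30 s).
#' @param collection_latency named list describing the click-to-collection
#'   latency distribution: `list(dist = "lognormal", meanlog, sdlog)`,
#'   `list(dist = "uniform", min, max)` or `list(dist = "constant", value)`.
#' @param depression_factor short-term depression per laser pulse, in `[0,1]`:
#'   the depression state is multiplied by `1 - depression_factor` at each
#'   pulse. `0` makes the evoked-response generator exactly linear.
#' @param depression_recovery_tau recovery time constant of the depression
#'   state toward 1, seconds.
#' @param spike_base_rate homogeneous firing rate of synthetic units, Hz.
#' @param spike_ramp_gain linear rate increase during the pre-approach ramp,
#'   Hz per second.
#' @param hazard_base baseline per-bin initiation hazard (250 ms bins).
#' @param hazard_profile named list: condition -> numeric vector of per-bin
#'   hazard multipliers (recycled to the number of bins; values must keep the
#'   hazard in `[0,1]`).
#' @param latency_cap observation cap for initiation latencies, seconds;
#'   trials that never initiate are recorded as censored at the cap.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(session_duration = 300,
                         seed = 1L,
                         sample_rate = 10000,
                         bleach_tau = 3600,
                         baseline_F = 1,
                         motion_sd = 0.03,
                         noise_sd = 0.01,
                         transient_kernel = c(rise = 0.05, decay = 0.5, amp = 0.05),
                         ramp_slope = 0.5,
                         ramp_duration = 1,
                         click_interval_range = c(15, 30),
                         collection_latency = list(dist = "lognormal",
                                                   meanlog = 0.7, sdlog = 0.6),
                         depression_factor = 0,
                         depression_recovery_tau = 1,
                         spike_base_rate = 10,
                         spike_ramp_gain = 10,
                         hazard_base = 0.15,
                         hazard_profile = list(vehicle = 1),
                         latency_cap = 10) {
  check_positive(session_duration, "session_duration")
  check_positive(sample_rate, "sample_rate")
  check_positive(bleach_tau, "bleach_tau")
  check_positive(baseline_F, "baseline_F")
  check_positive(ramp_duration, "ramp_duration")
  check_positive(depression_recovery_tau, "depression_recovery_tau")
  check_positive(latency_cap, "latency_cap")
  for (nm in c("motion_sd", "noise_sd", "ramp_slope", "spike_base_rate",
               "spike_ramp_gain", "hazard_base")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stopf("configuration error: `%s` must be a single non-negative number", nm)
  }
  tk <- transient_kernel
  if (length(tk) != 3L || any(!is.finite(tk)) || tk[[1]] <= 0 || tk[[2]] <= 0 ||
      tk[[1]] >= tk[[2]] || tk[[3]] < 0)
    stopf("configuration error: transient_kernel must be c(rise, decay, amp) with 0 < rise < decay and amp >= 0")
  names(tk) <- c("rise", "decay", "amp")
  if (length(click_interval_range) != 2L || any(click_interval_range <= 0) ||
      diff(click_interval_range) < 0)
    stopf("configuration error: click_interval_range must be increasing positive c(min, max)")
  if (depression_factor < 0 || depression_factor > 1)
    stopf("configuration error: depression_factor must lie in [0, 1]")
  if (!is.list(collection_latency) || is.null(collection_latency$dist))
    stopf("configuration error: collection_latency must name a distribution")
  if (!is.list(hazard_profile) || is.null(names(hazard_profile)))
    stopf("configuration error: hazard_profile must be a named list (condition -> multipliers)")
  structure(list(
    session_duration = session_duration, seed = as.integer(seed),
    sample_rate = sample_rate, bleach_tau = bleach_tau,
    baseline_F = baseline_F, motion_sd = motion_sd, noise_sd = noise_sd,
    transient_kernel = tk, ramp_slope = ramp_slope,
    ramp_duration = ramp_duration,
    click_interval_range = click_interval_range,
    collection_latency = collection_latency,
    depression_factor = depression_factor,
    depression_recovery_tau = depression_recovery_tau,
    spike_base_rate = spike_base_rate, spike_ramp_gain = spike_ramp_gain,
    hazard_base = hazard_base, hazard_profile = hazard_profile,
    latency_cap = latency_cap), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %.0f s session, seed %d, %g Hz detector\n",
              x$session_duration, x$seed, x$sample_rate))
  cat(sprintf("  transient rise/decay/amp = %.3g/%.3g/%.3g; ramp %.3g dF/F/s over %.3g s\n",
              x$transient_kernel[["rise"]], x$transient_kernel[["decay"]],
              x$transient_kernel[["amp"]], x$ramp_slope, x$ramp_duration))
  cat(sprintf("  motion_sd %.3g, noise_sd %.3g, bleach_tau %.0f s, depression %.2g\n",
              x$motion_sd, x$noise_sd, x$bleach_tau, x$depression_factor))
  invisible(x)
}

# Difference-of-exponentials transient, normalized to unit peak, zero for t<0.
transient_kernel_fn <- function(t, rise, decay) {
  k <- ifelse(t >= 0, exp(-t / decay) - exp(-t / rise), 0)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  k / (exp(-tpk / decay) - exp(-tpk / rise))
}

sample_collection_latency <- function(spec, n) {
  switch(spec$dist,
    lognormal = rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    uniform   = runif(n, min = spec$min, max = spec$max),
    constant  = rep(spec$value, n),
    stopf("unknown collection latency distribution '%s'", spec$dist))
}

# Low-pass Gaussian process on the raw sample grid: white noise on a 200 Hz
# grid smoothed with a Gaussian whose -3 dB point is ~2 Hz, rescaled to unit
# SD, linearly interpolated to the detector grid.
lowpass_motion <- function(t, sd_target) {
  if (sd_target <= 0) return(numeric(length(t)))
  grid_rate <- 200
  tg <- seq(0, max(t) + 1 / grid_rate, by = 1 / grid_rate)
  w <- rnorm(length(tg))
  sigma_s <- 0.1325 / 2            # Gaussian time-domain SD for a 2 Hz cutoff
  half <- ceiling(4 * sigma_s * grid_rate)
  kern <- dnorm(seq(-half, half) / grid_rate, sd = sigma_s)
  kern <- kern / sum(kern)
  m <- stats::filter(c(numeric(half), w, numeric(half)), kern, sides = 2)
  m <- as.numeric(m[(half + 1):(half + length(tg))])
  m <- (m - mean(m)) / sd(m) * sd_target
  approx(tg, m, xout = t, rule = 2)$y
}

# Compose the single-detector multiplexed stream from per-channel fluorescence
# vectors sampled on the full 10 kHz grid. Off-frame samples read dark (0);
# detector noise is added everywhere.
multiplex_stream <- function(F_by_channel, schedule, sample_rate, noise) {
  n <- length(F_by_channel[[1]])
  nch <- nrow(schedule$channels)
  spf <- round(sample_rate * schedule$frame_len)
  on_n <- round(sample_rate * schedule$on_len)
  n_frames <- floor(n / spf)
  raw <- numeric(n)
  fstart <- (seq_len(n_frames) - 1L) * spf
  ch_of_frame <- ((seq_len(n_frames) - 1L) %% nch) + 1L
  for (c in seq_len(nch)) {
    fs_c <- fstart[ch_of_frame == c]
    idx <- rep(fs_c, each = on_n) + seq_len(on_n)
    raw[idx] <- F_by_channel[[c]][idx]
  }
  raw + noise
}

#' Generate a synthetic Pavlovian (hopper-click) photometry session
#'
#' Emulates a session in which an unexpected food-hopper click occurs at
#' uniformly drawn 15-30 s intervals and the subject collects the pellet after
#' a variable latency. The true dF/F contains (i) a kernel-shaped transient at
#' each click and (ii) a linear ramp of slope `ramp_slope` ending exactly at
#' each food-port entry (the ramp spans the full `ramp_duration` even when
#' collection is faster, so the ground truth is exactly linear over the
#' analysis window on every trial). The raw detector stream is composed as
#' `baseline * exp(-t/bleach_tau) * (1 + dff_true + motion) + noise`, with the
#' motion artifact (but not `dff_true`) shared into the isosbestic channel,
#' then time-division multiplexed into a single stream.
#'
#' @param config a [synth_config()].
#' @param schedule an [led_schedule()]; default two channels
#'   (565 nm signal, 405 nm isosbestic).
#' @return A list with elements `raw` ([raw_photometry()]), `schedule`,
#'   `events` ([event_log()]), and `truth`: a list holding the latent
#'   `dff_true` and `motion` on the raw sample grid (`times`), plus the
#'   per-trial `click_times`, `portin_times` and `latencies`.
#' @export
generate_pavlovian_session <- function(config,
                                       schedule = led_schedule()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$session_duration <= max(config$click_interval_range))
    stopf("session_duration must exceed the maximum click interval")
  ss <- substream_seeds(config$seed)
  dur <- config$session_duration
  fs <- config$sample_rate

  clicks <- with_seed(ss[["events"]], {
    ts <- numeric(0); t <- 0
    repeat {
      t <- t + runif(1, config$click_interval_range[1], config$click_interval_range[2])
      if (t > dur - 2) break
      ts <- c(ts, t)
    }
    ts
  })
  lat <- with_seed(ss[["latencies"]],
                   sample_collection_latency(config$collection_latency, length(clicks)))
  portin <- clicks + lat
  keep <- portin <= dur - 0.5          # collections past session end are dropped
  portin_k <- portin[keep]

  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  tk <- config$transient_kernel

  dff <- numeric(n)
  if (tk[["amp"]] > 0) {
    span <- ceiling((tk[["decay"]] * 8) * fs)
    for (tc in clicks) {
      i0 <- floor(tc * fs) + 1L
      ii <- i0:min(n, i0 + span)
      dff[ii] <- dff[ii] + tk[["amp"]] *
        transient_kernel_fn(t[ii] - tc, tk[["rise"]], tk[["decay"]])
    }
  }
  if (config$ramp_slope > 0) {
    rd <- config$ramp_duration
    peak <- config$ramp_slope * rd
    tail_span <- ceiling(tk[["decay"]] * 8 * fs)
    for (tp in portin_k) {
      i1 <- max(1L, floor((tp - rd) * fs) + 1L)
      i2 <- min(n, floor(tp * fs) + 1L)
      dff[i1:i2] <- dff[i1:i2] + config$ramp_slope * (t[i1:i2] - (tp - rd))
      if (i2 < n) {                     # ramp releases with the kernel decay tau
        jj <- (i2 + 1L):min(n, i2 + tail_span)
        dff[jj] <- dff[jj] + peak * exp(-(t[jj] - tp) / tk[["decay"]])
      }
    }
  }

  motion <- with_seed(ss[["motion"]], lowpass_motion(t, config$motion_sd))
  noise <- if (config$noise_sd > 0)
    with_seed(ss[["noise"]], rnorm(n, sd = config$noise_sd * config$baseline_F))
  else numeric(n)

  bleach <- config$baseline_F * exp(-t / config$bleach_tau)
  nch <- nrow(schedule$channels)
  F_by_channel <- vector("list", nch)
  for (c in seq_len(nch)) {
    F_by_channel[[c]] <- if (isTRUE(schedule$channels$isosbestic[c]))
      bleach * (1 + motion) else bleach * (1 + dff + motion)
  }
  raw <- multiplex_stream(F_by_channel, schedule, fs, noise)

  ev <- rbind(
    data.frame(time_s = clicks, event_type = "click",
               trial_id = seq_along(clicks), extra = ""),
    data.frame(time_s = portin_k, event_type = "food_port_in",
               trial_id = which(keep),
               extra = sprintf("latency=%.4f", lat[keep])))
  ev <- ev[order(ev$time_s, ev$trial_id), ]
  events <- event_log(ev$time_s, ev$event_type, ev$trial_id,
                      condition = "pavlovian", extra = ev$extra)
  list(raw = raw_photometry(raw, fs), schedule = schedule, events = events,
       truth = list(times = t, dff_true = dff, motion = motion,
                    click_times = clicks, portin_times = portin_k,
                    latencies = lat[keep]))
}

#' Describe a laser stimulation train
#'
#' @param onset time of the first pulse, seconds.
#' @param pulse_width_ms pulse width, milliseconds.
#' @param power_mw laser power, milliwatts (metadata only; never used in
#'   computation).
#' @param frequency_hz pulse rate within the train, Hz.
#' @param n_pulses number of pulses.
#' @return Object of class `stim_train` with derived `pulse_times`.
#' @export
stim_train <- function(onset, pulse_width_ms = 4, power_mw = 10,
                       frequency_hz = 16, n_pulses = 1) {
  check_positive(pulse_width_ms, "pulse_width_ms")
  check_positive(frequency_hz, "frequency_hz")
  if (n_pulses < 1) stopf("n_pulses must be >= 1")
  structure(list(onset = onset, pulse_width_ms = pulse_width_ms,
                 power_mw = power_mw, frequency_hz = frequency_hz,
                 n_pulses = as.integer(n_pulses),
                 pulse_times = onset + (seq_len(n_pulses) - 1) / frequency_hz),
            class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train> t=%.3f s: %d pulse(s), %g ms @ %g Hz, %g mW\n",
              x$onset, x$n_pulses, x$pulse_width_ms, x$frequency_hz, x$power_mw))
  invisible(x)
}

#' Generate a synthetic optogenetic stimulation session
#'
#' Each laser pulse adds one response kernel (difference of exponentials,
#' unit peak) whose amplitude scales linearly with pulse width (normalized to
#' 4 ms) and with a depression state `s`: the pulse amplitude is
#' `amp * (width/4) * s`; immediately after each pulse `s` is multiplied by
#' `1 - depression_factor`, and between pulses it recovers toward 1 with time
#' constant `depression_recovery_tau`. With `depression_factor = 0` the evoked
#' response is exactly the linear superposition of identical single-pulse
#' kernels.
#'
#' @param config a [synth_config()].
#' @param protocol list of [stim_train()] objects; trains must not overlap.
#' @param schedule an [led_schedule()] (the optogenetics configuration is the
#'   same multiplexing machinery, typically two channels: 565/405).
#' @return List with `raw`, `schedule`, `events` (one `laser_pulse` event per
#'   pulse, `trial_id` = train index), and `truth` (`times`, `dff_true`,
#'   `motion`, per-pulse `amplitudes`).
#' @export
generate_stim_session <- function(config, protocol,
                                  schedule = led_schedule()) {
  stopifnot(inherits(config, "synth_config"))
  if (!length(protocol)) {
    pulses <- numeric(0); train_id <- integer(0); widths <- numeric(0)
  } else {
    if (!all(vapply(protocol, inherits, logical(1), "stim_train")))
      stopf("protocol must be a list of stim_train objects")
    ends <- vapply(protocol, function(tr) max(tr$pulse_times) + tr$pulse_width_ms / 1000, 0)
    starts <- vapply(protocol, function(tr) tr$onset, 0)
    o <- order(starts)
    if (any(starts[o][-1] < ends[o][-length(o)]))
      stopf("stimulation trains overlap")
    pulses <- unlist(lapply(protocol, function(tr) tr$pulse_times))
    train_id <- rep(seq_along(protocol),
                    vapply(protocol, function(tr) tr$n_pulses, 0L))
    widths <- rep(vapply(protocol, function(tr) tr$pulse_width_ms, 0),
                  vapply(protocol, function(tr) tr$n_pulses, 0L))
    ord <- order(pulses)
    pulses <- pulses[ord]; train_id <- train_id[ord]; widths <- widths[ord]
  }

  dur <- config$session_duration
  fs <- config$sample_rate
  n <- floor(dur * fs)
  t <- (seq_len(n) - 1) / fs
  tk <- config$transient_kernel

  # depression state across the whole session
  s <- 1; last <- -Inf
  amps <- numeric(length(pulses))
  for (i in seq_along(pulses)) {
    s <- 1 - (1 - s) * exp(-(pulses[i] - last) / config$depression_recovery_tau)
    amps[i] <- tk[["amp"]] * (widths[i] / 4) * s
    s <- s * (1 - config$depression_factor)
    last <- pulses[i]
  }

  dff <- numeric(n)
  span <- ceiling(tk[["decay"]] * 10 * fs)
  for (i in seq_along(pulses)) {
    i0 <- floor(pulses[i] * fs) + 1L
    if (i0 > n) next
    ii <- i0:min(n, i0 + span)
    dff[ii] <- dff[ii] + amps[i] *
      transient_kernel_fn(t[ii] - pulses[i], tk[["rise"]], tk[["decay"]])
  }

  ss <- substream_seeds(config$seed)
  motion <- with_seed(ss[["motion"]], lowpass_motion(t, config$motion_sd))
  noise <- if (config$noise_sd > 0)
    with_seed(ss[["noise"]], rnorm(n, sd = config$noise_sd * config$baseline_F))
  else numeric(n)
  bleach <- config$baseline_F * exp(-t / config$bleach_tau)
  nch <- nrow(schedule$channels)
  F_by_channel <- vector("list", nch)
  for (c in seq_len(nch)) {
    F_by_channel[[c]] <- if (isTRUE(schedule$channels$isosbestic[c]))
      bleach * (1 + motion) else bleach * (1 + dff + motion)
  }
  raw <- multiplex_stream(F_by_channel, schedule, fs, noise)

  events <- if (length(pulses))
    event_log(pulses, "laser_pulse", train_id, condition = "stim",
              extra = sprintf("width_ms=%g", widths))
  else event_log(numeric(0), character(0), integer(0))
  list(raw = raw_photometry(raw, fs), schedule = schedule, events = events,
       truth = list(times = t, dff_true = dff, motion = motion,
                    pulse_times = pulses, amplitudes = amps))
}

#' Generate a synthetic spike train
#'
#' Inhomogeneous-Poisson spikes by thinning. With `ramp = TRUE` the rate rises
#' linearly by `spike_ramp_gain` Hz/s over the `ramp_duration` preceding each
#' approach-completion event; otherwise the rate is homogeneous at
#' `spike_base_rate`.
#'
#' @param config a [synth_config()] (needs `spike_base_rate > 0`).
#' @param events an [event_log()] supplying the approach-completion events.
#' @param ramp logical; modulate the rate before each event?
#' @param event_type event type marking approach completion
#'   (default `"food_port_in"`).
#' @return Object of class `spike_train`: `unit_id`, `spike_times` (strictly
#'   increasing), and the latent `rate_fn(t)` used to generate them.
#' @export
generate_spike_train <- function(config, events, ramp = FALSE,
                                 event_type = "food_port_in") {
  stopifnot(inherits(config, "synth_config"))
  if (config$spike_base_rate <= 0)
    stopf("configuration error: spike_base_rate must be positive")
  te <- if (ramp) event_times(events, event_type) else numeric(0)
  base <- config$spike_base_rate
  gain <- config$spike_ramp_gain
  rd <- config$ramp_duration
  rate_fn <- function(t) {
    r <- rep(base, length(t))
    for (e in te) {
      in_ramp <- t >= (e - rd) & t <= e
      r[in_ramp] <- r[in_ramp] + gain * (t[in_ramp] - (e - rd))
    }
    r
  }
  rmax <- base + if (ramp) gain * rd else 0
  dur <- config$session_duration
  ss <- substream_seeds(config$seed)
  spikes <- with_seed(ss[["spikes"]], {
    n <- rpois(1, rmax * dur)
    cand <- sort(runif(n, 0, dur))
    cand[runif(n) < rate_fn(cand) / rmax]
  })
  structure(list(unit_id = sprintf("unit_seed%d", config$seed),
                 spike_times = spikes, rate_fn = rate_fn),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes", x$unit_id, length(x$spike_times)))
  if (length(x$spike_times))
    cat(sprintf(" over %.1f s (mean %.2f Hz)",
                max(x$spike_times),
                length(x$spike_times) / max(x$spike_times)))
  cat("\n")
  invisible(x)
}

#' Generate trial-initiation latencies by discrete-time hazard sampling
#'
#' Latencies are drawn bin-by-bin (250 ms bins): in bin `k` an uninitiated
#' trial initiates with probability `hazard_base * profile[k]`. Observation is
#' capped at `latency_cap` seconds; trials that never initiate are recorded
#' censored at the cap. Drug conditions suppress (or boost) the baseline
#' hazard via their per-bin multiplier profile.
#'
#' @param config a [synth_config()].
#' @param conditions character vector of condition labels; each must have an
#'   entry in `config$hazard_profile` (a profile of length 1 is recycled).
#' @param n_trials_per trials per condition.
#' @param n_subjects trials are split round-robin over this many subjects.
#' @param bin bin width, seconds (default 0.250).
#' @return A `latency_table` data.frame with columns
#'   `session_id,subject,condition,trial_id,latency_s,censored`, carrying the
#'   true per-bin hazards as attribute `"hazard_true"`.
#' @export
generate_pharm_latencies <- function(config, conditions, n_trials_per,
                                     n_subjects = 1, bin = 0.250) {
  stopifnot(inherits(config, "synth_config"))
  n_bins <- floor(config$latency_cap / bin)
  hz <- lapply(conditions, function(cond) {
    prof <- config$hazard_profile[[cond]]
    if (is.null(prof)) stopf("hazard_profile has no entry for condition '%s'", cond)
    h <- config$hazard_base * rep_len(prof, n_bins)
    if (any(h < 0 | h > 1))
      stopf("hazard values outside [0,1] for condition '%s'", cond)
    h
  })
  names(hz) <- conditions
  ss <- substream_seeds(config$seed)
  out <- with_seed(ss[["hazard"]], {
    rows <- lapply(conditions, function(cond) {
      h <- hz[[cond]]
      u <- matrix(runif(n_trials_per * n_bins), nrow = n_trials_per)
      hit <- sweep(u, 2, h, "<")
      first <- apply(hit, 1, function(z) { w <- which(z); if (length(w)) w[1] else NA_integer_ })
      censored <- is.na(first)
      within <- runif(n_trials_per)
      latency <- ifelse(censored, config$latency_cap,
                        (first - 1) * bin + within * bin)
      data.frame(session_id = paste0("sess_", cond),
                 subject = paste0("S", ((seq_len(n_trials_per) - 1) %% n_subjects) + 1),
                 condition = cond,
                 trial_id = seq_len(n_trials_per),
                 latency_s = latency,
                 censored = censored,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  class(out) <- c("latency_table", "data.frame")
  attr(out, "hazard_true") <- hz
  attr(out, "bin") <- bin
  out
}
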