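#' Stimulation-evoked response amplitude
#'
#' Peak of the baseline-subtracted trace in the response window following the
#' first pulse of a train; the baseline is the mean over the second preceding
#' the train.
#'
#' @param trace a [photo_trace()] (dF/F).
#' @param train a [stim_train()].
#' @param response_window window after the first pulse, seconds. Default:
#'   2 s for a single pulse, train duration + 2 s for a train.
#' @param baseline_len pre-train baseline length, seconds (default 1).
#' @param next_onset optional onset of the following train; the response
#'   window must end before it.
#' @return Peak dF/F (baseline-subtracted).
#' @export
evoked_amplitude <- function(trace, train, response_window = NULL,
                             baseline_len = 1, next_onset = NULL) {
  stopifnot(inherits(trace, "photo_trace"), inherits(train, "stim_train"))
  if (is.null(response_window))
    response_window <- (train$n_pulses - 1) / train$frequency_hz + 2
  on <- train$onset
  if (!is.null(next_onset) && on + response_window > next_onset)
    stopf("response window overlaps the next train (ends %.3f s, next at %.3f s)",
          on + response_window, next_onset)
  tt <- trace$times
  if (on - baseline_len < tt[1] - 1e-9 || on + response_window > tt[length(tt)] + 1e-9)
    stopf("train window not covered by the trace")
  base <- mean(trace$values[tt >= on - baseline_len & tt < on])
  resp <- trace$values[tt >= on & tt <= on + response_window]
  max(resp - base)
}

#' Paired-pulse amplitudes and ratio
#'
#' Isolates the second-pulse response by subtracting a single-pulse template,
#' scaled to the measured first-pulse amplitude and time-shifted to the
#' first-pulse onset, from the trace; the residual peak after the second
#' pulse is A2. Reports `(A1, A2, ratio = A2/A1)`; a ratio below 1 indicates
#' short-term depression.
#'
#' @param trace a [photo_trace()] containing the pulse-pair response.
#' @param pair a [stim_train()] with `n_pulses = 2`.
#' @param template a [photo_trace()] holding an isolated single-pulse
#'   response measured at matching width and power.
#' @param template_train the [stim_train()] of the template (for its onset).
#' @param response_window per-pulse measurement window, seconds (default 2).
#' @param noise_floor amplitudes at or below this are considered unmeasurable;
#'   the ratio is returned `NA` with `flagged = TRUE`.
#' @return List `A1`, `A2`, `ratio`, `flagged`.
#' @export
paired_pulse_amplitudes <- function(trace, pair, template, template_train,
                                    response_window = 2, noise_floor = 0) {
  stopifnot(inherits(pair, "stim_train"))
  if (pair$n_pulses != 2L) stopf("pair must have exactly 2 pulses")
  if (abs(pair$pulse_width_ms - template_train$pulse_width_ms) > 1e-9 ||
      abs(pair$power_mw - template_train$power_mw) > 1e-9)
    stopf("template width/power do not match the pulse pair")
  p1 <- pair$pulse_times[1]; p2 <- pair$pulse_times[2]
  tt <- trace$times
  base <- mean(trace$values[tt >= p1 - 1 & tt < p1])
  v <- trace$values - base

  # A1: peak between pulse 1 and pulse 2 (uncontaminated by pulse 2)
  A1 <- max(v[tt >= p1 & tt < p2])
  if (A1 <= noise_floor)
    return(list(A1 = A1, A2 = NA_real_, ratio = NA_real_, flagged = TRUE))

  # template response, baseline-subtracted, aligned to its own onset
  t0 <- template_train$onset
  tb <- mean(template$values[template$times >= t0 - 1 & template$times < t0])
  tmpl <- template$values[template$times >= t0] - tb
  tmpl_peak <- max(tmpl[seq_len(min(length(tmpl), round(response_window * template$rate)))])
  if (tmpl_peak <= 0) stopf("template has non-positive peak")
  tmpl <- tmpl * (A1 / tmpl_peak)

  # subtract the scaled template shifted to pulse-1 onset
  i1 <- round((p1 - tt[1]) * trace$rate) + 1L
  take <- min(length(tmpl), length(v) - i1 + 1L)
  resid <- v
  resid[i1:(i1 + take - 1L)] <- resid[i1:(i1 + take - 1L)] - tmpl[seq_len(take)]
  A2 <- max(resid[tt >= p2 & tt <= p2 + response_window])
  list(A1 = A1, A2 = A2, ratio = A2 / A1, flagged = FALSE)
}

#' Observed-vs-predicted linear-summation ratio
#'
#' Predicts the n-pulse train response by summating `n_pulses` copies of the
#' single-pulse response, each shifted by `1/frequency`, and reports
#' `observed peak / predicted peak`. A ratio near 1 indicates the absence of
#' short-term depression; depression pulls it below 1. Traces must be
#' baseline-subtracted responses aligned to the first pulse, on a common
#' uniform grid whose rate is commensurate with the pulse interval (true for
#' raw-rate ground-truth traces at standard train frequencies).
#'
#' @param observed numeric vector or [photo_trace()]: the measured n-pulse
#'   response.
#' @param single numeric vector or [photo_trace()]: the single-pulse
#'   response.
#' @param n_pulses number of pulses in the train.
#' @param frequency train frequency, Hz.
#' @param rate sampling rate, Hz (taken from the traces when omitted).
#' @return List `ratio`, `observed_peak`, `predicted_peak`, `predicted`
#'   (the predicted trace).
#' @export
summation_ratio <- function(observed, single, n_pulses, frequency,
                            rate = NULL) {
  if (inherits(observed, "photo_trace")) { rate <- observed$rate; observed <- observed$values }
  if (inherits(single, "photo_trace")) { if (is.null(rate)) rate <- single$rate; single <- single$values }
  if (is.null(rate)) stopf("sampling rate must be supplied for bare vectors")
  if (n_pulses < 1) stopf("n_pulses must be >= 1")
  shift_real <- rate / frequency
  shift <- round(shift_real)
  if (abs(shift_real - shift) > 1e-6)
    warning(sprintf("pulse interval is not an integer number of samples (%.6f); shifting by %d",
                    shift_real, shift))
  len <- length(single) + (n_pulses - 1L) * shift
  predicted <- numeric(len)
  for (k in seq_len(n_pulses) - 1L) {
    ii <- k * shift + seq_along(single)
    predicted[ii] <- predicted[ii] + single
  }
  ppk <- max(predicted)
  if (ppk <= 0) stopf("predicted peak is non-positive")
  opk <- max(observed)
  list(ratio = opk / ppk, observed_peak = opk, predicted_peak = ppk,
       predicted = predicted)
}
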