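# Generators: determinism, ground-truth access, degenerate configs,
# closed-form checks of the depression and hazard machinery.

quiet_cfg <- function(seed = 1, amp = 0, ...) {
  synth_config(session_duration = 60, seed = seed, motion_sd = 0,
               noise_sd = 0, ramp_slope = 0,
               transient_kernel = c(rise = 0.05, decay = 0.5, amp = amp), ...)
}

test_that("degenerate config gives zero dF/F and a pure bleaching exponential", {
  sess <- generate_pavlovian_session(quiet_cfg())
  expect_true(all(sess$truth$dff_true == 0))
  # during LED on-windows the detector reads baseline * exp(-t/tau) exactly
  sched <- sess$schedule
  fs <- 10000
  spf <- round(fs * sched$frame_len)
  on_n <- round(fs * sched$on_len)
  i_on <- 1:on_n                       # first frame, channel 1
  t_on <- (i_on - 1) / fs
  expect_equal(sess$raw$samples[i_on], exp(-t_on / 3600), tolerance = 1e-12)
  # off-window samples read dark
  expect_true(all(sess$raw$samples[(on_n + 1):spf] == 0))
})

test_that("identical config and seed reproduce the session bit-for-bit", {
  cfg <- synth_config(session_duration = 60, seed = 11)
  a <- generate_pavlovian_session(cfg)
  b <- generate_pavlovian_session(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$raw$samples, b$raw$samples)
  # substream isolation: turning noise off must not perturb the event schedule
  c <- generate_pavlovian_session(synth_config(session_duration = 60,
                                               seed = 11, noise_sd = 0))
  expect_identical(a$events, c$events)
})

test_that("approach ramp ground truth rises by slope * duration at port entry", {
  cfg <- synth_config(session_duration = 120, seed = 5, motion_sd = 0,
                      noise_sd = 0, ramp_slope = 0.5, ramp_duration = 1,
                      transient_kernel = c(rise = 0.05, decay = 0.5, amp = 0),
                      collection_latency = list(dist = "constant", value = 3))
  sess <- generate_pavlovian_session(cfg)
  expect_gt(length(sess$truth$portin_times), 2)
  for (tp in sess$truth$portin_times) {
    i2 <- round(tp * 10000) + 1L
    i1 <- round((tp - 1) * 10000) + 1L
    expect_equal(sess$truth$dff_true[i2] - sess$truth$dff_true[i1], 0.5,
                 tolerance = 1e-3)
  }
})

test_that("click intervals are uniform on the configured range", {
  cfg <- synth_config(session_duration = 2000, seed = 2, noise_sd = 0,
                      motion_sd = 0, ramp_slope = 0,
                      transient_kernel = c(rise = .05, decay = .5, amp = 0))
  sess <- generate_pavlovian_session(cfg)
  gaps <- diff(sess$truth$click_times)
  expect_gt(length(gaps), 50)
  expect_true(all(gaps >= 15 & gaps <= 30))
  expect_gt(mean(gaps), 20)  # centred, not piled at an edge
  expect_lt(mean(gaps), 25)
})

test_that("non-positive durations or taus are configuration errors", {
  expect_error(synth_config(session_duration = -1), "positive")
  expect_error(synth_config(bleach_tau = 0), "positive")
  expect_error(synth_config(transient_kernel = c(0.5, 0.05, 1)), "rise < decay")
  expect_error(synth_config(depression_factor = 1.5), "\\[0, 1\\]")
})

test_that("linear evoked generator superposes single-pulse responses exactly", {
  cfg <- quiet_cfg(amp = 0.05,
                   depression_factor = 0)
  single <- generate_stim_session(cfg, list(stim_train(10, frequency_hz = 16)))
  train <- generate_stim_session(cfg, list(stim_train(10, frequency_hz = 16,
                                                      n_pulses = 4)))
  fs <- 10000
  shift <- fs / 16
  manual <- numeric(length(single$truth$dff_true))
  for (k in 0:3) {
    src <- single$truth$dff_true
    n <- length(src)
    idx <- seq_len(n - k * shift)
    manual[idx + k * shift] <- manual[idx + k * shift] + src[idx]
  }
  expect_equal(train$truth$dff_true, manual, tolerance = 1e-12)
})

test_that("depression halves the second pulse amplitude when recovery is off", {
  cfg <- quiet_cfg(amp = 0.05,
                   depression_factor = 0.5, depression_recovery_tau = 1e9)
  sess <- generate_stim_session(cfg, list(stim_train(10, frequency_hz = 4,
                                                     n_pulses = 2)))
  amps <- sess$truth$amplitudes
  expect_equal(amps[2] / amps[1], 0.5, tolerance = 1e-6)
})

test_that("empty protocol yields no laser events and zero dF/F; overlap errors", {
  sess <- generate_stim_session(quiet_cfg(), list())
  expect_equal(nrow(sess$events), 0L)
  expect_true(all(sess$truth$dff_true == 0))
  expect_error(
    generate_stim_session(quiet_cfg(), list(
      stim_train(10, frequency_hz = 4, n_pulses = 4),
      stim_train(10.5, frequency_hz = 16))),
    "overlap")
})

test_that("homogeneous Poisson spike counts match the rate", {
  cfg <- synth_config(session_duration = 1000, seed = 3, spike_base_rate = 10)
  st <- generate_spike_train(cfg, event_log(numeric(0), character(0)),
                             ramp = FALSE)
  expect_true(abs(length(st$spike_times) - 10000) < 5 * sqrt(10000))
  expect_false(is.unsorted(st$spike_times, strictly = TRUE))
  expect_error(generate_spike_train(synth_config(spike_base_rate = 0),
                                    event_log(numeric(0), character(0))),
               "spike_base_rate")
})

test_that("ramp-modulated spike rate matches the closed-form peri-event mean", {
  # gain = base/ramp_duration doubles the rate at approach completion;
  # over the last 0.5 s the mean rate is base * (1 + mean of (t+1) on [0.5,1])
  # = base * 1.75
  events <- event_log(seq(20, 1980, by = 20), "food_port_in",
                      seq_along(seq(20, 1980, by = 20)))
  cfg <- synth_config(session_duration = 2000, seed = 8,
                      spike_base_rate = 10, spike_ramp_gain = 10,
                      ramp_duration = 1)
  st <- generate_spike_train(cfg, events, ramp = TRUE)
  te <- event_times(events, "food_port_in")
  n_in <- sum(vapply(te, function(e)
    sum(st$spike_times >= e - 0.5 & st$spike_times < e), 0))
  mean_rate <- n_in / (0.5 * length(te))
  expect_equal(mean_rate, 17.5, tolerance = 0.08)
  # the latent rate function agrees
  expect_equal(st$rate_fn(te[1] - 0.25), 17.5, tolerance = 1e-9)
})

test_that("constant hazard draws are geometric with the configured rate", {
  cfg <- synth_config(seed = 4, hazard_base = 0.2,
                      hazard_profile = list(c1 = 1))
  tab <- generate_pharm_latencies(cfg, "c1", n_trials_per = 10000)
  hz <- hazard_rate(tab)
  est <- hz$hazard[hz$at_risk > 500]
  expect_true(all(abs(est - 0.2) < 0.03))
  # censoring: everything uninitiated by the cap is censored at the cap
  expect_true(all(tab$latency_s[tab$censored] == 10))
})

test_that("zero hazard multiplier censors every trial", {
  cfg <- synth_config(seed = 4, hazard_profile = list(dead = 0))
  tab <- generate_pharm_latencies(cfg, "dead", n_trials_per = 200)
  expect_true(all(tab$censored))
})

test_that("hazard values outside [0,1] are rejected", {
  cfg <- synth_config(seed = 4, hazard_base = 0.5,
                      hazard_profile = list(bad = 3))
  expect_error(generate_pharm_latencies(cfg, "bad", 10), "outside \\[0,1\\]")
  expect_error(generate_pharm_latencies(synth_config(), "unknown", 10),
               "no entry")
})

test_that("two conditions with identical profiles differ only by sampling noise", {
  cfg <- synth_config(seed = 12, hazard_profile = list(a = 1, b = 1))
  tab <- generate_pharm_latencies(cfg, c("a", "b"), n_trials_per = 5000)
  la <- tab$latency_s[tab$condition == "a" & !tab$censored]
  lb <- tab$latency_s[tab$condition == "b" & !tab$censored]
  expect_gt(suppressWarnings(ks.test(la, lb))$p.value, 0.001)
})
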