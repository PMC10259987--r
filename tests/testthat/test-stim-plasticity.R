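# Evoked amplitudes, paired-pulse analysis, linear-summation ratio,
# repeated-measures ANOVA against the sum-of-squares oracle.

noiseless_cfg <- function(seed = 1, session_duration = 40, ...) {
  synth_config(session_duration = session_duration, seed = seed,
               motion_sd = 0, noise_sd = 0, ramp_slope = 0, ...)
}

truth_trace <- function(sess) {
  photo_trace(sess$truth$times, sess$truth$dff_true, units = "dF/F")
}

test_that("evoked amplitude recovers the injected single-pulse peak", {
  flat <- photo_trace(seq(0, 39.999, 1e-3), rep(0, 40000))
  tr1 <- stim_train(10)
  expect_equal(evoked_amplitude(flat, tr1), 0)
  sess <- generate_stim_session(noiseless_cfg(), list(tr1))
  expect_equal(evoked_amplitude(truth_trace(sess), tr1), 0.05,
               tolerance = 1e-6)
  expect_error(evoked_amplitude(truth_trace(sess), stim_train(39.5)),
               "not covered")
  expect_error(evoked_amplitude(truth_trace(sess), tr1, response_window = 5,
                                next_onset = 12), "overlaps")
})

test_that("pulse-width scaling is linear in the generator", {
  for (w in c(1, 2, 6)) {
    sess <- generate_stim_session(noiseless_cfg(),
                                  list(stim_train(10, pulse_width_ms = w)))
    expect_equal(evoked_amplitude(truth_trace(sess),
                                  stim_train(10, pulse_width_ms = w)),
                 0.05 * w / 4, tolerance = 1e-6)
  }
})

test_that("paired-pulse ratio is 1 for the linear generator and 0.5 under depression", {
  pair <- stim_train(20, frequency_hz = 2, n_pulses = 2)
  single <- stim_train(10)
  lin <- generate_stim_session(noiseless_cfg(), list(single, pair))
  pp <- paired_pulse_amplitudes(truth_trace(lin), pair, truth_trace(lin),
                                single)
  expect_false(pp$flagged)
  expect_equal(pp$ratio, 1, tolerance = 1e-3)
  dep <- generate_stim_session(
    noiseless_cfg(depression_factor = 0.5, depression_recovery_tau = 1e9),
    list(pair))
  lin1 <- generate_stim_session(noiseless_cfg(), list(single))
  pp2 <- paired_pulse_amplitudes(truth_trace(dep), pair, truth_trace(lin1),
                                 single)
  expect_equal(pp2$ratio, 0.5, tolerance = 5e-3)
})

test_that("template subtraction is negligible at long inter-pulse intervals", {
  # interval 10 s >> decay tau 0.5 s: the pulse-1 tail at pulse 2 is < 1e-8
  pair <- stim_train(10, frequency_hz = 0.1, n_pulses = 2)
  single <- stim_train(10)
  lin <- generate_stim_session(noiseless_cfg(session_duration = 40), list(pair))
  tmpl <- generate_stim_session(noiseless_cfg(), list(single))
  with_sub <- paired_pulse_amplitudes(truth_trace(lin), pair,
                                      truth_trace(tmpl), single)
  # A2 without any subtraction:
  v <- truth_trace(lin)
  base <- mean(v$values[v$times >= 9 & v$times < 10])
  a2_raw <- max(v$values[v$times >= 20 & v$times <= 22] - base)
  expect_lt(abs(with_sub$A2 - a2_raw) / a2_raw, 0.01)
})

test_that("flagged ratio when the first pulse is at the noise floor", {
  pair <- stim_train(20, frequency_hz = 2, n_pulses = 2)
  lin <- generate_stim_session(noiseless_cfg(), list(pair))
  pp <- paired_pulse_amplitudes(truth_trace(lin), pair, truth_trace(lin),
                                stim_train(20, n_pulses = 1),
                                noise_floor = 1)   # floor above any response
  expect_true(pp$flagged)
  expect_true(is.na(pp$ratio))
})

test_that("summation ratio is 1 for the linear generator and degrades with depression", {
  for (f in c(4, 8, 16)) {
    cfg <- noiseless_cfg()
    single <- generate_stim_session(cfg, list(stim_train(10, frequency_hz = f)))
    train <- generate_stim_session(cfg, list(stim_train(10, frequency_hz = f,
                                                        n_pulses = 4)))
    i0 <- round(10 * cfg$sample_rate) + 1L
    sr <- summation_ratio(train$truth$dff_true[i0:length(train$truth$dff_true)],
                          single$truth$dff_true[i0:length(single$truth$dff_true)],
                          4, f, rate = cfg$sample_rate)
    expect_equal(sr$ratio, 1, tolerance = 1e-6)
  }
  # one pulse predicts itself
  cfg <- noiseless_cfg()
  single <- generate_stim_session(cfg, list(stim_train(10)))
  i0 <- round(10 * cfg$sample_rate) + 1L
  v <- single$truth$dff_true[i0:length(single$truth$dff_true)]
  expect_equal(summation_ratio(v, v, 1, 16, rate = cfg$sample_rate)$ratio, 1)
  # monotone degradation in depression_factor
  ratios <- vapply(c(0, 0.25, 0.5, 0.75), function(d) {
    cfg_d <- noiseless_cfg(depression_factor = d, depression_recovery_tau = 1e6)
    tr <- generate_stim_session(cfg_d, list(stim_train(10, frequency_hz = 8,
                                                       n_pulses = 4)))
    sg <- generate_stim_session(noiseless_cfg(), list(stim_train(10, frequency_hz = 8)))
    summation_ratio(tr$truth$dff_true[i0:length(tr$truth$dff_true)],
                    sg$truth$dff_true[i0:length(sg$truth$dff_true)],
                    4, 8, rate = cfg$sample_rate)$ratio
  }, 0)
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[3], 1)
})

test_that("one-way repeated-measures ANOVA matches the SS oracle", {
  # textbook-style 3-level, 4-subject table
  y <- matrix(c(5, 6, 7,
                4, 6, 8,
                6, 7, 9,
                5, 8, 8), nrow = 3)          # level x subject
  tab <- data.frame(subject = rep(1:4, each = 3), level = rep(1:3, 4),
                    value = as.vector(y))
  got <- one_way_rm_anova(tab)
  want <- oracle_rm_anova(y)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(c(got$df1, got$df2), c(2, 6))
  # all levels identical per subject -> F = 0
  flat <- data.frame(subject = rep(1:4, each = 3), level = rep(1:3, 4),
                     value = rep(c(2, 5, 1, 7), each = 3))
  expect_equal(one_way_rm_anova(flat)$F, 0)
  # df structure (3, 12) at k = 4 levels, n = 5 subjects
  t45 <- data.frame(subject = rep(1:5, each = 4), level = rep(1:4, 5),
                    value = rnorm(20))
  got45 <- one_way_rm_anova(t45)
  expect_equal(c(got45$df1, got45$df2), c(3, 12))
  expect_error(one_way_rm_anova(t45[-1, ]), "unbalanced")
})

test_that("two-way repeated-measures ANOVA matches the oracle and df (2,6)", {
  set.seed(21)
  y <- array(rnorm(2 * 3 * 4, mean = 5), dim = c(2, 3, 4))  # order x interval x subject
  tab <- expand.grid(factor1 = 1:2, factor2 = 1:3, subject = 1:4)
  tab$value <- as.vector(y)
  got <- two_way_rm_anova(tab)
  want <- oracle_rm_anova2(y)
  expect_equal(got$interaction$F, want$AB$F, tolerance = 1e-8)
  expect_equal(got$factor1$F, want$A$F, tolerance = 1e-8)
  expect_equal(got$factor2$F, want$B$F, tolerance = 1e-8)
  expect_equal(c(got$interaction$df1, got$interaction$df2), c(2, 6))
  # all-equal data -> every F is 0
  tab0 <- tab; tab0$value <- 1
  got0 <- two_way_rm_anova(tab0)
  expect_equal(got0$interaction$F, 0)
  expect_equal(got0$factor1$F, 0)
  expect_error(two_way_rm_anova(tab[-1, ]), "unbalanced")
})
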