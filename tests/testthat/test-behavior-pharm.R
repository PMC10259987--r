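# Completed-trial counting, latency CDF, hazard machinery,
# per-bin permutation test, condition ANOVA with post-hoc contrasts.

test_that("completed trials require the full event sequence and no timeout", {
  log <- make_operant_log(n = 3, n_timeout = 1)
  expect_equal(as.integer(completed_trials(log)), 3L)
  empty <- event_log(numeric(0), character(0))
  expect_equal(as.integer(completed_trials(empty)), 0L)
  # out-of-order trial is malformed, reported, not silently dropped
  bad <- event_log(c(1, 2, 3, 4), c("center_in", "light_on", "go_cue", "choice_in"),
                   rep(1L, 4))
  expect_warning(n <- completed_trials(bad), "malformed")
  expect_equal(as.integer(n), 0L)
  expect_equal(attr(n, "malformed"), 1L)
})

test_that("latency CDF bins at 250 ms, filters at 1 s, normalizes to the retained set", {
  tab <- data.frame(session_id = "s", subject = "S1", condition = "vehicle",
                    trial_id = 1:3, latency_s = c(1.1, 1.3, 2.0),
                    censored = FALSE)
  cdf <- latency_cdf(tab)
  expect_equal(cdf$cdf[cdf$bin_end == 2.0], 1)
  expect_equal(cdf$cdf[cdf$bin_end == 1.25], 1 / 3)
  # adding a sub-threshold latency changes nothing
  tab2 <- rbind(tab, data.frame(session_id = "s", subject = "S1",
                                condition = "vehicle", trial_id = 4,
                                latency_s = 0.5, censored = FALSE))
  expect_equal(latency_cdf(tab2), cdf)
  expect_error(latency_cdf(tab2[4, , drop = FALSE]), "remain")
})

test_that("geometric latencies reproduce the closed-form CDF", {
  cfg <- synth_config(seed = 17, hazard_base = 0.2,
                      hazard_profile = list(c1 = 1))
  tab <- generate_pharm_latencies(cfg, "c1", n_trials_per = 10000)
  cdf <- latency_cdf(tab, min_latency = 0)
  k <- seq_len(sum(cdf$bin_end <= 8))
  # conditional on initiating before the cap
  p_cap <- 1 - (1 - 0.2)^40
  expect_equal(cdf$cdf[k], (1 - (1 - 0.2)^k) / p_cap, tolerance = 0.02)
})

test_that("hazard curve obeys the risk-set recursion and truncates cleanly", {
  tab <- data.frame(session_id = "s", subject = "S1", condition = "x",
                    trial_id = 1:5,
                    latency_s = c(0.1, 0.3, 0.3, 0.6, 1.4),
                    censored = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  hz <- hazard_rate(tab)
  expect_equal(hz$at_risk[1], 5)
  expect_equal(hz$hazard[1], 1 / 5)
  expect_equal(hz$hazard[2], 2 / 4)
  expect_equal(hz$hazard[3], 1 / 2)
  with_ev <- hz$events + hz$censored
  expect_equal(hz$at_risk[-1], (hz$at_risk - with_ev)[-length(hz$at_risk)])
  expect_equal(sum(hz$events) + sum(hz$censored), hz$at_risk[1])
  # all latencies in one bin: hazard 1 there, undefined after
  one <- tab[1:3, ]; one$latency_s <- 0.3; one$censored <- FALSE
  expect_message(h1 <- hazard_rate(one, n_bins = 4), "truncated")
  expect_equal(h1$hazard[2], 1)
  expect_true(all(is.na(h1$hazard[3:4])))
})

test_that("hazard-reconstructed CDF equals the direct CDF bin-for-bin", {
  cfg <- synth_config(seed = 23, hazard_profile = list(a = 1))
  tab <- generate_pharm_latencies(cfg, "a", n_trials_per = 3000)
  tab_u <- tab[!tab$censored, , drop = FALSE]
  hz <- hazard_rate(tab_u)
  direct <- latency_cdf(tab_u, min_latency = 0)
  expect_equal(cdf_from_hazard(hz), direct$cdf, tolerance = 1e-12)
})

test_that("exponential latencies give a flat hazard", {
  lat <- phramp:::with_seed(31, rexp(10000, rate = 0.9))
  tab <- data.frame(session_id = "s", subject = "S1", condition = "exp",
                    trial_id = seq_along(lat), latency_s = lat,
                    censored = FALSE)
  hz <- hazard_rate(tab)
  use <- which(hz$at_risk >= 200)
  mids <- (head(hz$bin_edges, -1) + tail(hz$bin_edges, -1)) / 2
  fit <- lm(hz$hazard[use] ~ mids[use])
  expect_lt(abs(coef(fit)[2]), 0.01)   # per-second trend of a per-bin hazard
  expect_equal(mean(hz$hazard[use]), 1 - exp(-0.9 * 0.25), tolerance = 0.04)
})

test_that("per-bin permutation test flags a localized hazard suppression", {
  tab <- make_pharm_table(seed = 41, n = 4000, mult = c(vehicle = 1, drug = 0.5),
                          drug_bins = 5:8)
  res <- per_bin_condition_test(tab, reference = "vehicle", n_perm = 600,
                                seed = 42)
  in_window <- res$bin_start >= 1 & res$bin_end <= 2
  expect_true(all(res$flagged[in_window]))
  expect_lt(sum(res$flagged[!in_window], na.rm = TRUE), 3)
  # estimated hazard ratio in the suppressed bins is about 0.5
  hz <- hazard_rate(tab)
  hr <- hz$drug$hazard[5:8] / hz$vehicle$hazard[5:8]
  expect_equal(mean(hr), 0.5, tolerance = 0.1)
})

test_that("permutation flags are seed-reproducible and order-invariant", {
  tab <- make_pharm_table(seed = 43, n = 600, mult = c(vehicle = 1, drug = 0.6))
  a <- per_bin_condition_test(tab, n_perm = 300, seed = 7)
  b <- per_bin_condition_test(tab, n_perm = 300, seed = 7)
  expect_identical(a, b)
  tab_rev <- tab[rev(seq_len(nrow(tab))), ]
  c_ <- per_bin_condition_test(tab_rev, n_perm = 300, seed = 7)
  expect_equal(sort(c_$bin_start[c_$flagged]), sort(a$bin_start[a$flagged]))
  expect_error(per_bin_condition_test(tab[tab$condition == "vehicle", ]),
               "2 conditions")
  expect_error(per_bin_condition_test(tab, reference = "nope"), "absent")
})

test_that("condition ANOVA reuses the RM machinery and Holm post-hocs find the deficit", {
  set.seed(51)
  subjects <- sprintf("r%02d", 1:13)
  mk <- function(cond, mu) data.frame(subject = subjects, condition = cond,
                                      count = round(rnorm(13, mu, 15)))
  counts <- rbind(mk("vehicle", 300), mk("dhbe15", 285), mk("dhbe30", 220),
                  mk("flu", 150))
  res <- condition_anova(counts)
  expect_equal(c(res$anova$df1, res$anova$df2), c(3, 36))
  expect_lt(res$anova$p, 1e-4)
  ph <- res$posthoc
  expect_lt(ph$p_holm[ph$condition == "flu"], 0.01)
  expect_lt(ph$p_holm[ph$condition == "dhbe30"], 0.01)
  expect_true(all(ph$mean_diff[ph$condition %in% c("dhbe30", "flu")] < 0))
  # identical counts -> F = 0
  flat <- counts; flat$count <- rep(100, nrow(flat))
  expect_equal(condition_anova(flat)$anova$F, 0)
  expect_error(condition_anova(counts[-1, ]), "unbalanced|missing")
})
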