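# Independent oracles and small fixture builders, used across test files.

# Brute-force max-min slope: explicit scan for the first-occurring extrema,
# slope from their actual times. Independent of the vectorized path.
oracle_maxmin_slope <- function(values, times) {
  imax <- 1L; imin <- 1L
  for (i in seq_along(values)) {
    if (values[i] > values[imax]) imax <- i
    if (values[i] < values[imin]) imin <- i
  }
  if (imax == imin) return(0)
  (values[imax] - values[imin]) / (times[imax] - times[imin])
}

# Brute-force one-way repeated-measures ANOVA from the sum-of-squares
# decomposition (k levels x n subjects, one value per cell).
oracle_rm_anova <- function(y) {           # y: k x n matrix (level x subject)
  k <- nrow(y); n <- ncol(y)
  gm <- mean(y)
  ss_cond <- n * sum((rowMeans(y) - gm)^2)
  ss_subj <- k * sum((colMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# Brute-force two-way repeated-measures decomposition; y[a, b, s].
oracle_rm_anova2 <- function(y) {
  a <- dim(y)[1]; b <- dim(y)[2]; n <- dim(y)[3]
  gm <- mean(y)
  mA <- apply(y, 1, mean); mB <- apply(y, 2, mean); mS <- apply(y, 3, mean)
  mAB <- apply(y, c(1, 2), mean)
  mAS <- apply(y, c(1, 3), mean)
  mBS <- apply(y, c(2, 3), mean)
  ss_A <- b * n * sum((mA - gm)^2)
  ss_B <- a * n * sum((mB - gm)^2)
  ss_AB <- n * sum((mAB - outer(mA, rep(1, b)) - outer(rep(1, a), mB) + gm)^2)
  ss_AS <- b * sum((mAS - outer(mA, rep(1, n)) - outer(rep(1, a), mS) + gm)^2)
  ss_BS <- a * sum((mBS - outer(mB, rep(1, n)) - outer(rep(1, b), mS) + gm)^2)
  resid <- y
  for (i in 1:a) for (j in 1:b) for (s in 1:n)
    resid[i, j, s] <- y[i, j, s] - mAB[i, j] - mAS[i, s] - mBS[j, s] +
      mA[i] + mB[j] + mS[s] - gm
  ss_ABS <- sum(resid^2)
  f <- function(ss, df, sse, dfe) (ss / df) / (sse / dfe)
  list(
    A = list(F = f(ss_A, a - 1, ss_AS, (a - 1) * (n - 1)),
             df1 = a - 1, df2 = (a - 1) * (n - 1)),
    B = list(F = f(ss_B, b - 1, ss_BS, (b - 1) * (n - 1)),
             df1 = b - 1, df2 = (b - 1) * (n - 1)),
    AB = list(F = f(ss_AB, (a - 1) * (b - 1), ss_ABS, (a - 1) * (b - 1) * (n - 1)),
              df1 = (a - 1) * (b - 1), df2 = (a - 1) * (b - 1) * (n - 1)))
}

# White-noise trace on a uniform grid, for trace-level shuffle-test work.
make_noise_trace <- function(duration = 300, rate = 50, sd = 0.002,
                             seed = NULL) {
  n <- duration * rate
  v <- if (is.null(seed)) rnorm(n, sd = sd) else
    phramp:::with_seed(seed, rnorm(n, sd = sd))
  photo_trace((seq_len(n) - 1) / rate, v, units = "dF/F")
}

# Add event-locked linear ramps (slope over `dur` ending at each event).
add_ramps <- function(trace, events, slope, dur = 1) {
  v <- trace$values
  for (e in events) {
    ii <- which(trace$times >= e - dur & trace$times < e)
    v[ii] <- v[ii] + slope * (trace$times[ii] - (e - dur))
  }
  photo_trace(trace$times, v, units = trace$units)
}

# A small well-formed operant event log: `n` completed trials plus
# `n_timeout` trials aborted by timeout.
make_operant_log <- function(n = 3, n_timeout = 1) {
  rows <- list()
  t <- 0
  tid <- 0L
  for (i in seq_len(n + n_timeout)) {
    tid <- tid + 1L
    is_to <- i > n
    t <- t + 5
    rows[[length(rows) + 1L]] <- data.frame(
      time_s = t + c(0, 1, 1.5, 2),
      event_type = c("light_on", "center_in", "go_cue",
                     if (is_to) "timeout" else "choice_in"),
      trial_id = tid)
    t <- t + 3
  }
  d <- do.call(rbind, rows)
  event_log(d$time_s, d$event_type, d$trial_id)
}

# Fast pharmacology fixture: two-condition latency table from the generator.
make_pharm_table <- function(seed, n = 2000, mult = c(vehicle = 1, drug = 1),
                             drug_bins = 5:8, n_subjects = 4) {
  prof_drug <- rep(1, 40)
  prof_drug[drug_bins] <- mult[["drug"]]
  cfg <- synth_config(seed = seed,
                      hazard_profile = list(vehicle = rep(mult[["vehicle"]], 40),
                                            drug = prof_drug))
  generate_pharm_latencies(cfg, c("vehicle", "drug"), n_trials_per = n,
                           n_subjects = n_subjects)
}
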