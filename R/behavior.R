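#' Count completed operant trials
#'
#' A completed trial contains `light_on`, then `center_in`, then `go_cue`,
#' then `choice_in` in order, with no `timeout` event; a timeout (e.g.
#' failure to hold until the go cue) disqualifies the trial. Trials whose
#' events violate the required ordering are reported as malformed rather than
#' silently dropped.
#'
#' @param events an [event_log()] for one session.
#' @return Integer count, with attributes `malformed` (trial ids whose event
#'   sequence is inconsistent) and `n_trials` (distinct trials seen).
#' @export
completed_trials <- function(events) {
  tids <- unique(events$trial_id[!is.na(events$trial_id)])
  done <- 0L
  malformed <- integer(0)
  for (tid in tids) {
    ev <- events[!is.na(events$trial_id) & events$trial_id == tid, ]
    first_of <- function(type) {
      t <- ev$time_s[ev$event_type == type]
      if (length(t)) t[1] else NA_real_
    }
    t4 <- c(first_of("light_on"), first_of("center_in"),
            first_of("go_cue"), first_of("choice_in"))
    has_timeout <- any(ev$event_type == "timeout")
    if (all(!is.na(t4))) {
      if (is.unsorted(t4)) { malformed <- c(malformed, tid); next }
      if (!has_timeout) done <- done + 1L
    }
  }
  if (length(malformed))
    warning("malformed trial sequence(s): ", paste(malformed, collapse = ", "))
  structure(done, malformed = malformed, n_trials = length(tids))
}

# Right-closed bins ((k-1)*bin, k*bin]: a latency exactly on an edge belongs
# to the bin it ends (survival-analysis convention).
latency_bin_index <- function(latency_s, bin)
  pmax(1L, as.integer(ceiling(latency_s / bin - 1e-9)))

#' Cumulative distribution of long latencies
#'
#' Empirical CDF of uncensored latencies greater than `min_latency`, binned
#' at `bin`-second resolution and normalized to the retained set, computed
#' per condition.
#'
#' @param table a `latency_table`.
#' @param bin bin width, seconds (default 0.250).
#' @param min_latency retain only latencies strictly greater than this
#'   (default 1.0 s, the long-latency convention).
#' @return data.frame with columns `condition`, `bin_start`, `bin_end`,
#'   `count`, `cdf`.
#' @export
latency_cdf <- function(table, bin = 0.250, min_latency = 1.0) {
  keep <- !table$censored & table$latency_s > min_latency
  if (!any(keep)) stopf("no latencies remain after the > %g s filter", min_latency)
  tb <- table[keep, , drop = FALSE]
  n_bins <- max(latency_bin_index(tb$latency_s, bin))
  out <- lapply(unique(tb$condition), function(cond) {
    l <- tb$latency_s[tb$condition == cond]
    counts <- tabulate(latency_bin_index(l, bin), nbins = n_bins)
    data.frame(condition = cond,
               bin_start = (seq_len(n_bins) - 1) * bin,
               bin_end = seq_len(n_bins) * bin,
               count = counts,
               cdf = cumsum(counts) / length(l),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Discrete hazard rate of initiation latencies
#'
#' Per-bin hazard `events_in_bin / at_risk`, where censored trials leave the
#' risk set at their censoring bin without counting as events. The risk set
#' obeys `at_risk[i+1] = at_risk[i] - events[i] - censored[i]`. If the risk
#' set empties mid-curve the remaining bins are `NA` and a notice is given.
#'
#' @param table a `latency_table` (pass a filtered table for
#'   long-latency-conditional hazards).
#' @param bin bin width, seconds (default 0.250).
#' @param condition optional single condition to select; default computes one
#'   curve per condition present.
#' @param n_bins number of bins; default spans up to the latest latency.
#' @return A `hazard_curve` (or a named list of them when several conditions
#'   are present): `bin_edges`, `hazard`, `events`, `censored`, `at_risk`,
#'   `condition`.
#' @export
hazard_rate <- function(table, bin = 0.250, condition = NULL, n_bins = NULL) {
  if (!is.null(condition)) table <- table[table$condition == condition, , drop = FALSE]
  conds <- unique(table$condition)
  if (!nrow(table)) stopf("empty latency table")
  if (length(conds) > 1L) {
    out <- lapply(conds, function(cc) hazard_rate(table, bin, cc, n_bins))
    names(out) <- conds
    return(out)
  }
  bins <- latency_bin_index(table$latency_s, bin)
  if (is.null(n_bins)) n_bins <- max(bins)
  ev <- tabulate(bins[!table$censored], nbins = n_bins)
  cn <- tabulate(bins[table$censored], nbins = n_bins)
  at_risk <- nrow(table) - cumsum(c(0, (ev + cn)[-n_bins]))
  hz <- ifelse(at_risk > 0, ev / at_risk, NA_real_)
  if (anyNA(hz))
    message(sprintf("risk set empties at bin %d; hazard truncated",
                    which(is.na(hz))[1]))
  structure(list(bin_edges = seq(0, n_bins) * bin, hazard = hz, events = ev,
                 censored = cn, at_risk = at_risk, condition = conds,
                 bin = bin),
            class = "hazard_curve")
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf("<hazard_curve> '%s': %d bins of %g s, %d trials at risk\n",
              x$condition, length(x$hazard), x$bin, x$at_risk[1]))
  invisible(x)
}

#' @export
plot.hazard_curve <- function(x, ...) {
  mids <- (head(x$bin_edges, -1) + tail(x$bin_edges, -1)) / 2
  graphics::plot(mids, x$hazard, type = "s", xlab = "latency (s)",
                 ylab = "hazard / bin", main = x$condition, ...)
  invisible(x)
}

#' Reconstruct a CDF from a hazard curve
#'
#' `F(k) = 1 - prod_{i<=k} (1 - h_i)`; bin-for-bin consistent with the
#' directly computed empirical CDF when no censoring intervenes.
#'
#' @param curve a `hazard_curve`.
#' @return Numeric vector of per-bin cumulative probabilities.
#' @export
cdf_from_hazard <- function(curve) {
  stopifnot(inherits(curve, "hazard_curve"))
  1 - cumprod(1 - curve$hazard)
}

# events / censored / at_risk tabulation used by the permutation test
.haz_counts <- function(bins, censored, n_bins) {
  ev <- tabulate(bins[!censored], nbins = n_bins)
  cn <- tabulate(bins[censored], nbins = n_bins)
  at_risk <- length(bins) - cumsum(c(0, (ev + cn)[-n_bins]))
  list(ev = ev, at_risk = at_risk)
}

#' Per-bin permutation test against a reference condition
#'
#' For each latency bin, tests whether a condition's hazard (or CDF) differs
#' from the reference by permuting condition labels across trials within
#' subject. Two-sided p-values use the `(1 + k) / (1 + B)` estimator; bins
#' with `p < alpha` are flagged. Bin-wise tests are uncorrected by design
#' (matching per-bin significance marks on hazard/CDF figures).
#'
#' @param table a `latency_table` covering the reference and at least one
#'   other condition (per-trial data: the test resamples trials, not curves).
#' @param reference reference condition label (default `"vehicle"`).
#' @param bin bin width, seconds.
#' @param alpha flagging threshold (default 0.01).
#' @param n_perm permutations (default 10000).
#' @param seed optional seed.
#' @param statistic `"hazard"` or `"cdf"` per-bin difference.
#' @param min_at_risk bins where either group's risk set is smaller than this
#'   are not tested (default 10).
#' @return data.frame `condition, bin_start, bin_end, observed_diff, p,
#'   flagged` (one row per tested bin and non-reference condition).
#' @export
per_bin_condition_test <- function(table, reference = "vehicle", bin = 0.250,
                                   alpha = 0.01, n_perm = 10000, seed = NULL,
                                   statistic = c("hazard", "cdf"),
                                   min_at_risk = 10) {
  statistic <- match.arg(statistic)
  conds <- unique(table$condition)
  if (length(conds) < 2L) stopf("need at least 2 conditions")
  if (!reference %in% conds) stopf("reference condition '%s' absent", reference)
  others <- setdiff(conds, reference)

  per_bin_stat <- function(bins, censored, n_bins) {
    hc <- .haz_counts(bins, censored, n_bins)
    h <- ifelse(hc$at_risk > 0, hc$ev / hc$at_risk, NA_real_)
    if (statistic == "cdf") 1 - cumprod(1 - ifelse(is.na(h), 0, h)) else h
  }

  out <- lapply(others, function(cond) {
    sel <- table$condition %in% c(reference, cond)
    tb <- table[sel, , drop = FALSE]
    # canonical row order so the permutation stream (and hence the flags)
    # does not depend on how the caller ordered the trials
    tb <- tb[order(tb$subject, tb$condition, tb$trial_id, tb$latency_s), ,
             drop = FALSE]
    bins <- latency_bin_index(tb$latency_s, bin)
    n_bins <- max(bins)
    is_cond <- tb$condition == cond
    s_c <- per_bin_stat(bins[is_cond], tb$censored[is_cond], n_bins)
    s_r <- per_bin_stat(bins[!is_cond], tb$censored[!is_cond], n_bins)
    obs <- s_c - s_r
    rk_c <- .haz_counts(bins[is_cond], tb$censored[is_cond], n_bins)$at_risk
    rk_r <- .haz_counts(bins[!is_cond], tb$censored[!is_cond], n_bins)$at_risk
    testable <- rk_c >= min_at_risk & rk_r >= min_at_risk & !is.na(obs)

    subj <- tb$subject
    count_ge <- numeric(n_bins)
    n_used <- 0L
    with_seed(seed, {
      subj_idx <- split(seq_len(nrow(tb)), subj)
      for (p in seq_len(n_perm)) {
        lab <- is_cond
        for (ii in subj_idx) lab[ii] <- is_cond[ii][sample.int(length(ii))]
        d <- per_bin_stat(bins[lab], tb$censored[lab], n_bins) -
             per_bin_stat(bins[!lab], tb$censored[!lab], n_bins)
        count_ge <- count_ge + as.numeric(!is.na(d) & !is.na(obs) &
                                          abs(d) >= abs(obs) - 1e-12)
        n_used <- n_used + 1L
      }
    })
    p_two <- (1 + count_ge) / (1 + n_used)
    data.frame(condition = cond,
               bin_start = (seq_len(n_bins) - 1) * bin,
               bin_end = seq_len(n_bins) * bin,
               observed_diff = obs,
               p = ifelse(testable, p_two, NA_real_),
               flagged = testable & p_two < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Completed-trial ANOVA with post-hoc contrasts against vehicle
#'
#' One-way repeated-measures ANOVA of per-session completed-trial counts
#' across treatment conditions (df `(k-1, (k-1)(n-1))`; 4 conditions over 13
#' subjects give (3, 36)), followed by paired post-hoc comparisons of each
#' drug condition against vehicle with Holm correction.
#'
#' @param counts data.frame with columns `subject`, `condition`, `count`;
#'   every subject must have every condition (counterbalanced within-subject
#'   design).
#' @param reference reference condition (default `"vehicle"`).
#' @return List `anova` (an `rm_anova`) and `posthoc` (data.frame
#'   `condition, mean_diff, t, df, p, p_holm`).
#' @export
condition_anova <- function(counts, reference = "vehicle") {
  if (!all(c("subject", "condition", "count") %in% names(counts)))
    stopf("counts must have columns subject, condition, count")
  if (!reference %in% counts$condition)
    stopf("reference condition '%s' absent", reference)
  an <- one_way_rm_anova(data.frame(subject = counts$subject,
                                    level = counts$condition,
                                    value = counts$count))
  subjects <- sort(unique(counts$subject))
  val <- function(cond) {
    v <- counts$count[match(paste(subjects, cond),
                            paste(counts$subject, counts$condition))]
    if (anyNA(v)) stopf("missing cells for condition '%s'", cond)
    v
  }
  ref <- val(reference)
  others <- setdiff(unique(counts$condition), reference)
  ph <- lapply(others, function(cond) {
    v <- val(cond)
    tt <- t.test(v, ref, paired = TRUE)
    data.frame(condition = cond, mean_diff = mean(v - ref),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, ph)
  ph$p_holm <- p.adjust(ph$p, method = "holm")
  list(anova = an, posthoc = ph)
}
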