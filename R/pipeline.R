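#' Default pipeline configuration
#'
#' Flat key-value run configuration. Analysis defaults follow the standard
#' conventions used throughout the package: 0.5 s ramp window, 1.0 s peak
#' window, 1000 shuffles, 250 ms latency bins, 1.0 s long-latency threshold.
#'
#' @param ... overrides of the default keys.
#' @return Named list of configuration values.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    session_duration = 120,
    ramp_window = 0.5,
    peak_window = 1.0,
    n_shuffles = 1000,
    bin = 0.250,
    min_latency = 1.0,
    ramp_slope = 0.5,
    transient_amp = 0.05,
    motion_sd = 0.03,
    noise_sd = 0.01,
    n_pharm_trials = 500,
    pharm_conditions = c("vehicle", "dhbe15", "dhbe30", "flu"),
    stim_frequencies = c(4, 8, 16),
    stim_n_pulses = 4)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_run_config, y)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a shared configuration, writing stage outputs
#' as CSVs with stable schemas plus a run log (seeds, versions, row counts)
#' and the resolved configuration. Subcommand `"all"` chains
#' simulate -> preprocess -> align -> ramp-test -> stim -> behavior on a
#' synthetic session. Everything is deterministic under a fixed seed.
#'
#' @param subcommand one of `"simulate"`, `"preprocess"`, `"align"`,
#'   `"ramp-test"`, `"stim"`, `"behavior"`, `"all"`.
#' @param config a configuration list from [default_run_config()], or a path
#'   to a YAML file of overrides.
#' @param out_dir output directory for this run; must not already contain a
#'   run unless `force = TRUE`.
#' @param force overwrite an existing run directory.
#' @return (invisibly) character vector of files written.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "preprocess",
                                        "align", "ramp-test", "stim",
                                        "behavior"),
                         config = default_run_config(), out_dir = "phramp_run",
                         force = FALSE) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- read_run_config(config)
  }
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stopf("output directory '%s' is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  pth <- function(f) file.path(out_dir, f)

  yaml::write_yaml(config, emit(pth("config_resolved.yaml")))
  log_lines <- c(sprintf("phramp %s", as.character(utils::packageVersion("phramp"))),
                 sprintf("subcommand: %s", subcommand),
                 sprintf("seed: %d", config$seed))

  stages <- if (subcommand == "all")
    c("simulate", "preprocess", "align", "ramp-test", "stim", "behavior")
  else subcommand

  sc <- synth_config(session_duration = config$session_duration,
                     seed = config$seed, ramp_slope = config$ramp_slope,
                     transient_kernel = c(rise = 0.05, decay = 0.5,
                                          amp = config$transient_amp),
                     motion_sd = config$motion_sd, noise_sd = config$noise_sd,
                     hazard_profile = list(
                       vehicle = 1,
                       dhbe15 = c(rep(1, 4), rep(0.75, 4), rep(1, 32)),
                       dhbe30 = c(rep(1, 4), rep(0.5, 4), rep(1, 32)),
                       flu = c(rep(1, 4), rep(0.4, 4), rep(1, 32))))

  for (stage in stages) {
    if (stage == "simulate") {
      sess <- generate_pavlovian_session(sc)
      write_raw_photometry(sess$raw, emit(pth("raw_photometry.csv")))
      write_led_schedule(sess$schedule, emit(pth("led_schedule.yaml")))
      write_event_log(sess$events, emit(pth("events.csv")))
      data.table::fwrite(data.frame(time_s = sess$truth$times,
                                    dff_true = sess$truth$dff_true),
                         emit(pth("dff_true.csv")))
      log_lines <- c(log_lines, sprintf("simulate: %d events, %d raw samples",
                                        nrow(sess$events), length(sess$raw$samples)))
    } else if (stage == "preprocess") {
      for (f in c("raw_photometry.csv", "led_schedule.yaml", "events.csv"))
        if (!file.exists(pth(f))) stopf("missing input '%s' for preprocess", pth(f))
      raw <- read_raw_photometry(pth("raw_photometry.csv"))
      sched <- read_led_schedule(pth("led_schedule.yaml"))
      chans <- demultiplex(raw, sched)
      iso <- which(sched$channels$isosbestic)[1]
      sig <- which(!sched$channels$isosbestic)[1]
      corrected <- isosbestic_correct(chans[[sig]], chans[[iso]])
      write_trace(corrected, emit(pth("corrected_dff.csv")))
      log_lines <- c(log_lines, sprintf("preprocess: %d frames per channel",
                                        length(corrected$values)))
    } else if (stage == "align") {
      if (!file.exists(pth("corrected_dff.csv")))
        stopf("missing input '%s' for align", pth("corrected_dff.csv"))
      trace <- read_trace(pth("corrected_dff.csv"))
      events <- read_event_log(pth("events.csv"))
      for (evt in c("click", "food_port_in")) {
        m <- sort_by_latency(align_trace(trace, events, evt,
                                         window = c(2, 2)))
        d <- cbind(data.frame(trial_id = m$trial_meta$trial_id),
                   as.data.frame(m$data))
        data.table::fwrite(d, emit(pth(sprintf("aligned_%s.csv", evt))))
        data.table::fwrite(m$trial_meta, emit(pth(sprintf("aligned_%s_meta.csv", evt))))
      }
      log_lines <- c(log_lines, "align: click + food_port_in matrices")
    } else if (stage == "ramp-test") {
      if (!file.exists(pth("corrected_dff.csv")))
        stopf("missing input '%s' for ramp-test", pth("corrected_dff.csv"))
      trace <- read_trace(pth("corrected_dff.csv"))
      events <- read_event_log(pth("events.csv"))
      lat <- extract_latencies(events, "click", "food_port_in",
                               min_latency = config$min_latency)
      portin <- events$time_s[events$event_type == "food_port_in" &
                              events$trial_id %in% lat$trial_id]
      res <- list(
        approach_ramp = shuffle_test(trace, portin, "maxmin_slope",
                                     window = config$ramp_window,
                                     n_shuffles = config$n_shuffles,
                                     seed = config$seed + 1L),
        click_peak = shuffle_test(trace,
                                  events$time_s[events$event_type == "click"],
                                  "peak", window = config$peak_window,
                                  n_shuffles = config$n_shuffles,
                                  seed = config$seed + 2L))
      write_shuffle_results(res, emit(pth("ramp_test_results.csv")))
      log_lines <- c(log_lines, sprintf("ramp-test: slope sig=%s, peak sig=%s",
                                        res[[1]]$significant, res[[2]]$significant))
    } else if (stage == "stim") {
      rows <- list()
      for (f in config$stim_frequencies) {
        scs <- synth_config(session_duration = 30, seed = config$seed,
                            noise_sd = 0, motion_sd = 0)
        single <- generate_stim_session(scs, list(stim_train(5, frequency_hz = f)))
        train <- generate_stim_session(scs, list(
          stim_train(5, frequency_hz = f, n_pulses = config$stim_n_pulses)))
        i5 <- round(5 * scs$sample_rate) + 1L
        sr <- summation_ratio(train$truth$dff_true[i5:length(train$truth$dff_true)],
                              single$truth$dff_true[i5:length(single$truth$dff_true)],
                              config$stim_n_pulses, f, rate = scs$sample_rate)
        rows[[length(rows) + 1L]] <- data.frame(
          frequency_hz = f, n_pulses = config$stim_n_pulses,
          observed_peak = sr$observed_peak, predicted_peak = sr$predicted_peak,
          summation_ratio = sr$ratio)
      }
      data.table::fwrite(do.call(rbind, rows), emit(pth("summation_ratios.csv")))
      log_lines <- c(log_lines, sprintf("stim: %d frequencies", length(config$stim_frequencies)))
    } else if (stage == "behavior") {
      lt <- generate_pharm_latencies(sc, config$pharm_conditions,
                                     n_trials_per = config$n_pharm_trials,
                                     n_subjects = 4, bin = config$bin)
      write_latency_table(lt, emit(pth("latency_table.csv")))
      cdf <- latency_cdf(lt, bin = config$bin, min_latency = config$min_latency)
      data.table::fwrite(cdf, emit(pth("latency_cdf.csv")))
      hz <- hazard_rate(lt, bin = config$bin)
      hzd <- do.call(rbind, lapply(hz, function(h)
        data.frame(condition = h$condition,
                   bin_start = head(h$bin_edges, -1),
                   bin_end = tail(h$bin_edges, -1),
                   hazard = h$hazard, at_risk = h$at_risk)))
      data.table::fwrite(hzd, emit(pth("hazard_curves.csv")))
      flags <- per_bin_condition_test(lt, reference = "vehicle",
                                      bin = config$bin, n_perm = 1000,
                                      seed = config$seed + 3L)
      data.table::fwrite(flags, emit(pth("hazard_flags.csv")))
      log_lines <- c(log_lines, sprintf("behavior: %d trials x %d conditions",
                                        config$n_pharm_trials,
                                        length(config$pharm_conditions)))
    }
  }
  writeLines(log_lines, emit(pth("run_log.txt")))
  invisible(written)
}
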