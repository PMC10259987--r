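#' Read / write session artifacts as CSV
#'
#' All tabular artifacts are plain CSVs with headers, written and read with
#' \pkg{data.table}: event logs (`time_s,event_type,trial_id,condition,extra`),
#' raw photometry (`time_s,detector_v`), traces (`time_s,dff` or
#' `time_s,value`), ground truth (`time_s,dff_true`) and latency tables
#' (`session_id,subject,condition,trial_id,latency_s,censored`). LED
#' schedules travel as flat key-value YAML.
#'
#' @param x object to write.
#' @param path file path.
#' @name phramp-io
NULL

#' @rdname phramp-io
#' @export
write_event_log <- function(x, path) {
  data.table::fwrite(as.data.frame(unclass(x)), path)
  invisible(path)
}

#' @rdname phramp-io
#' @export
read_event_log <- function(path) {
  d <- data.table::fread(path, data.table = FALSE,
                         colClasses = list(character = c("event_type", "condition", "extra")))
  event_log(d$time_s, d$event_type, d$trial_id, d$condition, d$extra)
}

#' @rdname phramp-io
#' @export
write_raw_photometry <- function(x, path) {
  stopifnot(inherits(x, "raw_photometry"))
  t <- x$t0 + (seq_along(x$samples) - 1) / x$sample_rate
  data.table::fwrite(data.frame(time_s = t, detector_v = x$samples), path)
  invisible(path)
}

#' @rdname phramp-io
#' @export
read_raw_photometry <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  dt <- diff(d$time_s[1:2])
  raw_photometry(d$detector_v, sample_rate = round(1 / dt), t0 = d$time_s[1])
}

#' @rdname phramp-io
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "photo_trace"))
  col <- if (x$units == "dF/F") "dff" else "value"
  d <- data.frame(time_s = x$times, v = x$values)
  names(d)[2] <- col
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname phramp-io
#' @export
read_trace <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  units <- if (names(d)[2] == "dff") "dF/F" else "a.u."
  photo_trace(d[[1]], d[[2]], units = units)
}

#' @rdname phramp-io
#' @export
write_latency_table <- function(x, path) {
  data.table::fwrite(as.data.frame(unclass(x)), path)
  invisible(path)
}

#' @rdname phramp-io
#' @export
read_latency_table <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  class(d) <- c("latency_table", "data.frame")
  d
}

#' @rdname phramp-io
#' @export
write_led_schedule <- function(x, path) {
  stopifnot(inherits(x, "led_schedule"))
  yaml::write_yaml(list(frame_len = x$frame_len, on_len = x$on_len,
                        channels = x$channels$label,
                        wavelength_nm = x$channels$wavelength_nm,
                        isosbestic = x$channels$isosbestic), path)
  invisible(path)
}

#' @rdname phramp-io
#' @export
read_led_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  led_schedule(y$frame_len, y$on_len,
               data.frame(label = unlist(y$channels),
                          wavelength_nm = unlist(y$wavelength_nm),
                          isosbestic = unlist(y$isosbestic)))
}

#' Write a shuffle-test results table
#'
#' Schema: `recording_id,statistic,observed,ci_lo,ci_hi,significant,
#' direction,n_shuffles,seed`.
#'
#' @param results named list of `shuffle_test_result` objects.
#' @param path file path.
#' @export
write_shuffle_results <- function(results, path) {
  tally <- count_significant(results)
  tab <- tally$table
  tab$n_shuffles <- vapply(results, function(r) r$n_shuffles, 0)
  tab$seed <- vapply(results, function(r) if (is.null(r$seed)) NA_real_ else r$seed, 0)
  data.table::fwrite(tab, path)
  invisible(path)
}
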