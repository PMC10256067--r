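#' Pipeline configuration
#'
#' All tunables of the decode-and-control pipeline in one validated object.
#' Every source of randomness downstream flows from the single `seed`.
#'
#' @param sampling_rate insole sampling rate in Hz (default 100).
#' @param filter a [filter_params()].
#' @param scan_time scan window length b in seconds (default 1.5).
#' @param margin_factor threshold safety margin (default 1.1).
#' @param calibration_seconds length of the press-free lead-in segment of a
#'   trace used to calibrate the threshold (default 3).
#' @param level_map a [distance_level_map()].
#' @param full_open_time full-open time t_A in seconds (default 2).
#' @param poly_order polynomial degree for the posture fit, or `"auto"` to
#'   pick it by [select_order()] (default `"auto"`).
#' @param seed integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sampling_rate = 100,
                            filter = filter_params(),
                            scan_time = 1.5,
                            margin_factor = 1.1,
                            calibration_seconds = 3,
                            level_map = distance_level_map(),
                            full_open_time = 2,
                            poly_order = "auto",
                            seed = 1L) {
  stopifnot(inherits(filter, "filter_params"),
            inherits(level_map, "distance_level_map"))
  if (sampling_rate <= 0) stop("invalid sampling_rate: must be > 0")
  if (scan_time <= 0) stop("invalid scan_time: must be > 0")
  if (margin_factor < 1) stop("invalid margin_factor: must be >= 1")
  if (calibration_seconds <= 0) stop("invalid calibration_seconds: must be > 0")
  if (full_open_time <= 0) stop("invalid full_open_time: must be > 0")
  if (!identical(poly_order, "auto")) {
    poly_order <- as.integer(poly_order)
    if (is.na(poly_order) || poly_order < 1L) {
      stop("invalid poly_order: must be >= 1 or \"auto\"")
    }
  }
  structure(list(sampling_rate = sampling_rate,
                 filter = filter,
                 scan_time = scan_time,
                 margin_factor = margin_factor,
                 calibration_seconds = calibration_seconds,
                 level_map = level_map,
                 full_open_time = full_open_time,
                 poly_order = poly_order,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_fields <- c("sampling_rate", "filter", "scan_time", "margin_factor",
                    "calibration_seconds", "levels", "full_open_time",
                    "poly_order", "seed")
.filter_fields <- c("window_length", "F", "B", "H", "Q", "R", "x0", "P0")

#' Save a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(sampling_rate = config$sampling_rate,
            filter = config$filter[.filter_fields],
            scan_time = config$scan_time,
            margin_factor = config$margin_factor,
            calibration_seconds = config$calibration_seconds,
            levels = as.list(config$level_map$levels),
            full_open_time = config$full_open_time,
            poly_order = config$poly_order,
            seed = config$seed)
  x$filter$x0 <- if (is.null(config$filter$x0)) "first_sample" else config$filter$x0
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Round-trip inverse of [save_config()]. Unknown keys and missing required
#' fields are rejected by name; out-of-range values fail with the field
#' name in the message.
#'
#' @param path input file path.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), .config_fields)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(.config_fields, names(x))
  if (length(missing)) {
    stop("missing config field(s): ", paste(missing, collapse = ", "))
  }
  unknown_f <- setdiff(names(x$filter), .filter_fields)
  if (length(unknown_f)) {
    stop("unknown filter key(s): ", paste(unknown_f, collapse = ", "))
  }
  if (x$filter$window_length < 1) {
    stop("invalid window_length: must be >= 1")
  }
  x0 <- x$filter$x0
  if (identical(x0, "first_sample")) x0 <- NULL
  fp <- filter_params(window_length = x$filter$window_length,
                      F = x$filter$F, B = x$filter$B, H = x$filter$H,
                      Q = x$filter$Q, R = x$filter$R,
                      x0 = x0, P0 = x$filter$P0)
  lv <- unlist(x$levels)
  pipeline_config(sampling_rate = x$sampling_rate,
                  filter = fp,
                  scan_time = x$scan_time,
                  margin_factor = x$margin_factor,
                  calibration_seconds = x$calibration_seconds,
                  level_map = distance_level_map(lv),
                  full_open_time = x$full_open_time,
                  poly_order = x$poly_order,
                  seed = x$seed)
}

#' Generate a daily-activity scenario trace
#'
#' Standing-regime traces whose hallux press choreography mirrors common
#' daily tasks, each with a press-free 3 s lead-in for threshold
#' calibration. Presses are brief (0.25 s) deliberate toe taps:
#' \describe{
#'   \item{drink_water}{one-time grasp: press to open and grab the cup,
#'     press again to release it — 2 presses, 2 openings.}
#'   \item{tie_shoelaces}{continuous bimanual task with 4 grasp phases — 4
#'     presses, closing between each.}
#'   \item{take_off_coat}{long continuous task — 6 presses.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed for the sensor noise.
#' @param specs channel specifications (default [default_channel_specs()]).
#' @param sampling_rate sampling rate in Hz.
#' @return a [force_trace()] with attribute `press_onsets`.
#' @export
scenario_trace <- function(name = c("drink_water", "tie_shoelaces",
                                    "take_off_coat"),
                           seed = 1L,
                           specs = default_channel_specs(),
                           sampling_rate = 100) {
  name <- match.arg(name)
  onsets <- switch(name,
    drink_water   = c(3.6, 9.1),
    tie_shoelaces = c(3.6, 6.6, 9.6, 12.6),
    take_off_coat = 3.6 + 3 * (0:5)
  )
  duration <- max(onsets) + 4.4
  tr <- generate_trace(gait_spec("standing"), specs = specs,
                       presses = press_schedule(onsets, 0.25, "hallux"),
                       duration = duration, sampling_rate = sampling_rate,
                       seed = seed)
  attr(tr, "press_onsets") <- onsets
  tr
}

#' Run the whole pipeline on a trace
#'
#' Composes the stages end to end: calibrate the threshold on the trace's
#' press-free lead-in, fit the posture polynomial from the packaged
#' opening-time data, decode presses per scan window and drive the
#' simulated hand. Equivalent to calling the stages by hand.
#'
#' @param config a [pipeline_config()].
#' @param trace a [force_trace()], or a path to a trace file readable by
#'   [read_trace()].
#' @param channel control channel name.
#' @return list with `log` (the [run_closed_loop()] log), `windows`
#'   (per-window press counts), `summary` (list: `n_windows`,
#'   `total_presses`, `n_open`, `n_close`, `final_openness_mm`,
#'   `threshold`), `model` and `calibration`.
#' @export
run_pipeline <- function(config, trace, channel = "hallux") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(trace)) {
    trace <- tryCatch(read_trace(trace),
                      error = function(e) stop("[read] ", conditionMessage(e)))
  }
  stopifnot(inherits(trace, "force_trace"))
  calib <- tryCatch({
    n_cal <- min(nrow(trace$channels),
                 round(config$calibration_seconds * trace$sampling_rate))
    baseline <- filter_trace(trace, channel, config$filter)[seq_len(n_cal)]
    calibrate_threshold(baseline, config$margin_factor, regime = "standing",
                        window = c(trace$start_time,
                                   trace$start_time + n_cal / trace$sampling_rate))
  }, error = function(e) stop("[calibrate] ", conditionMessage(e)))
  model <- tryCatch({
    data <- hand_opening_times(config$full_open_time)
    ord <- if (identical(config$poly_order, "auto")) {
      select_order(data)$order
    } else {
      config$poly_order
    }
    fit_polynomial(data, ord)
  }, error = function(e) stop("[fit] ", conditionMessage(e)))
  log <- tryCatch(
    run_closed_loop(trace, calib, model, config$level_map,
                    scan_time = config$scan_time, params = config$filter,
                    channel = channel, t_full = config$full_open_time),
    error = function(e) stop("[control] ", conditionMessage(e))
  )
  win <- attr(log, "windows")
  list(log = log,
       windows = win,
       summary = list(n_windows = nrow(win),
                      total_presses = sum(win$S),
                      n_open = sum(log$line_a == "high"),
                      n_close = sum(log$line_b == "high"),
                      final_openness_mm = attr(log, "final_state")$openness,
                      threshold = calib$threshold),
       model = model,
       calibration = calib)
}

#' Write a control log as line-delimited JSON
#'
#' One JSON record per command, suitable for appending and for diffing
#' between runs.
#'
#' @param log a [run_closed_loop()] log.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_control_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
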