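#' Hand state
#'
#' The assistive hand is a single-degree-of-freedom gripper: its whole
#' posture is the interfinger distance (openness) in mm, 0 (closed) to 100
#' (fully open). The phase is derived: closed at 0 mm, open otherwise.
#'
#' @param openness interfinger distance in mm, in \[0, 100\].
#' @return an object of class `hand_state` with fields `openness`, `phase`.
#' @export
hand_state <- function(openness = 0) {
  stopifnot(openness >= 0, openness <= 100)
  structure(list(openness = as.numeric(openness),
                 phase = if (openness == 0) "closed" else "open"),
            class = "hand_state")
}

#' @export
print.hand_state <- function(x, ...) {
  cat("<hand_state>", x$phase, "at", format(x$openness, digits = 4), "mm\n")
  invisible(x)
}

#' Press-count to distance level map
#'
#' Five-level posture code sized for common objects: 1 press opens to
#' 25 mm, 2 to 50 mm, 3 to 75 mm, 4 or more to the full 100 mm; no press in
#' a cycle while the hand is open closes it. Five levels keep the code easy
#' to memorise while covering most graspable object sizes.
#'
#' @param levels named numeric vector mapping press counts `"1"`..`"4"` to
#'   target distances in mm; must be strictly increasing and end at 100.
#' @return an object of class `distance_level_map`.
#' @export
distance_level_map <- function(levels = c(`1` = 25, `2` = 50,
                                          `3` = 75, `4` = 100)) {
  stopifnot(length(levels) >= 1, all(diff(levels) > 0))
  if (utils::tail(levels, 1) != 100) {
    stop("the top press level must open fully (100 mm)")
  }
  structure(list(levels = levels, max_count = length(levels)),
            class = "distance_level_map")
}

#' Map a window's press count to a target openness
#'
#' One or more presses in a data cycle command the corresponding level
#' (counts above the top level saturate at full open); zero presses while
#' the hand is open command closure; zero presses while closed is a no-op.
#'
#' @param S press count decoded from one scan window, >= 0.
#' @param state current [hand_state()].
#' @param map a [distance_level_map()].
#' @return target openness in mm, or `NA` for a no-op.
#' @export
map_presses <- function(S, state, map = distance_level_map()) {
  stopifnot(S >= 0, inherits(state, "hand_state"),
            inherits(map, "distance_level_map"))
  if (S >= 1) {
    return(unname(map$levels[min(S, map$max_count)]))
  }
  if (state$phase == "open") return(0)
  NA_real_
}

#' Plan an open/close line command
#'
#' The hand is driven by two lines: A high with B low opens, A low with B
#' high closes, both low holds. (Both high is undefined and never emitted.)
#' With no position feedback, posture is reached by timing: the duration to
#' travel from the current openness to the target is the difference of their
#' opening times under the fitted calibration, quantised to the command
#' tick. Closing is assumed to traverse the same time-distance curve.
#'
#' @param state current [hand_state()].
#' @param target target openness in mm, in \[0, 100\].
#' @param model a [posture_model()].
#' @param t_full full-open time t_A in seconds.
#' @param tick command-duration quantum in seconds (default 0.01).
#' @return an object of class `control_command` with fields `line_a`,
#'   `line_b` (`"high"`/`"low"`) and `duration` (s).
#' @export
plan_command <- function(state, target, model,
                         t_full = model$full_open_time, tick = 0.01) {
  stopifnot(inherits(state, "hand_state"))
  if (target < 0 || target > 100) stop("target outside the 0-100 mm span")
  dt <- opening_time(model, target, t_full) -
    opening_time(model, state$openness, t_full)
  duration <- round(abs(dt) / tick) * tick
  if (duration == 0) {
    cmd <- list(line_a = "low", line_b = "low", duration = 0)
  } else if (dt > 0) {
    cmd <- list(line_a = "high", line_b = "low", duration = duration)
  } else {
    cmd <- list(line_a = "low", line_b = "high", duration = duration)
  }
  structure(cmd, class = "control_command")
}

#' @export
print.control_command <- function(x, ...) {
  verb <- if (x$line_a == "high") "open" else if (x$line_b == "high") "close" else "hold"
  cat("<control_command>", verb, "for", format(x$duration, digits = 4), "s",
      "(A", x$line_a, "/ B", x$line_b, ")\n")
  invisible(x)
}

# Inverse of the fitted ratio curve on [0, 100] by bisection; the Table-5
# fit is monotone increasing on the span, and ratios outside the curve's
# range clamp to the nearest end stop.
invert_ratio <- function(model, d) {
  d0 <- predict_ratio(model, 0)
  d1 <- predict_ratio(model, 100)
  if (d <= d0) return(0)
  if (d >= d1) return(100)
  stats::uniroot(function(l) predict_ratio(model, l) - d,
                 interval = c(0, 100), tol = 1e-9)$root
}

#' Advance the simulated hand under one command
#'
#' The plant model of the hand: driving the open (close) line for a duration
#' moves the mechanism along the calibration curve by `duration / t_A` in
#' time-ratio, and the resulting openness is the inverse of the fitted
#' curve, clamped to the mechanical end stops. Hold leaves the state
#' unchanged.
#'
#' @param state current [hand_state()].
#' @param cmd a [plan_command()] result.
#' @param model a [posture_model()].
#' @param t_full full-open time t_A in seconds.
#' @return the new [hand_state()].
#' @export
step_plant <- function(state, cmd, model, t_full = model$full_open_time) {
  stopifnot(inherits(state, "hand_state"), inherits(cmd, "control_command"))
  if (cmd$line_a == "high" && cmd$line_b == "high") {
    stop("line A and line B may not both be high")
  }
  if (cmd$line_a == "low" && cmd$line_b == "low") return(state)
  sign <- if (cmd$line_a == "high") 1 else -1
  d <- predict_ratio(model, state$openness) + sign * cmd$duration / t_full
  hand_state(invert_ratio(model, d))
}

#' Replay a trace through the full decode-and-control loop
#'
#' Runs the complete pipeline on a recorded or simulated trace: filter the
#' hallux channel, decode presses per scan window, map counts to posture
#' targets, plan timed line commands and advance the simulated hand. The
#' log is append-only and fully determined by the inputs.
#'
#' @param trace a [force_trace()].
#' @param calibration a [calibrate_threshold()] result.
#' @param model a [posture_model()].
#' @param map a [distance_level_map()].
#' @param scan_time scan window length in seconds.
#' @param params a [filter_params()].
#' @param channel control channel name.
#' @param t_full full-open time t_A in seconds.
#' @return data frame of class `control_log`, one row per non-hold command:
#'   `window`, `S`, `target_mm`, `line_a`, `line_b`, `duration_s`,
#'   `openness_mm` (after the command). The final hand state is attached as
#'   attribute `final_state`, the per-window counts as attribute `windows`.
#' @export
run_closed_loop <- function(trace, calibration, model,
                            map = distance_level_map(),
                            scan_time = 1.5,
                            params = filter_params(),
                            channel = "hallux",
                            t_full = model$full_open_time) {
  win <- stream_windows(trace, channel, calibration, scan_time, params)
  state <- hand_state(0)
  rows <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    target <- map_presses(win$S[w], state, map)
    if (is.na(target)) next
    cmd <- plan_command(state, target, model, t_full)
    if (cmd$duration == 0) next
    state <- step_plant(state, cmd, model, t_full)
    rows[[w]] <- data.frame(window = win$window[w], S = win$S[w],
                            target_mm = target,
                            line_a = cmd$line_a, line_b = cmd$line_b,
                            duration_s = cmd$duration,
                            openness_mm = state$openness)
  }
  log <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(log)) {
    log <- data.frame(window = integer(), S = integer(),
                      target_mm = numeric(), line_a = character(),
                      line_b = character(), duration_s = numeric(),
                      openness_mm = numeric())
  }
  structure(log, class = c("control_log", "data.frame"),
            final_state = state, windows = win)
}
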