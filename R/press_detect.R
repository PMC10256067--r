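#' Calibrate the per-user press threshold
#'
#' Body weight and foot shape differ between users, so the force threshold
#' that separates deliberate presses from ordinary loading is derived from
#' each user's own data: the maximum of a press-free segment (recorded while
#' walking, standing or sitting) times a safety margin. Everything below the
#' threshold — gait peaks, resting load, incidental toe contact — is
#' shielded from press counting.
#'
#' @param baseline numeric press-free force sequence (filtered scale),
#'   non-empty with a positive maximum.
#' @param margin_factor multiplicative safety margin, >= 1 (default 1.1;
#'   thresholds are deliberately conservative).
#' @param regime which activity the baseline was recorded in:
#'   `"standing"`, `"walking"` or `"sitting"`.
#' @param window optional `(start_s, end_s)` provenance of the baseline.
#' @return an object of class `press_calibration` with fields `threshold`,
#'   `margin_factor`, `regime`, `window`.
#' @export
calibrate_threshold <- function(baseline, margin_factor = 1.1,
                                regime = c("standing", "walking", "sitting"),
                                window = NULL) {
  regime <- match.arg(regime)
  if (length(baseline) == 0L) stop("empty baseline sequence")
  stopifnot(margin_factor >= 1)
  m <- max(baseline)
  if (m <= 0) {
    stop("baseline maximum is not positive; an unloaded sensor gives no usable threshold")
  }
  structure(list(threshold = margin_factor * m,
                 margin_factor = margin_factor,
                 regime = regime,
                 window = window),
            class = "press_calibration")
}

#' @export
print.press_calibration <- function(x, ...) {
  cat("<press_calibration> threshold =", format(x$threshold, digits = 6),
      "(margin", x$margin_factor, "on", x$regime, "baseline)\n")
  invisible(x)
}

# Strict threshold crossings: indices i (2..N) where the segment
# (a[i-1], a[i]) crosses t, i.e. (a[i-1]-t)*(a[i]-t) < 0. Samples exactly on
# the threshold never cross (g(x >= 0) = 0), so tangential touches do not
# count.
threshold_crossings <- function(a, t) {
  which((a[-length(a)] - t) * (a[-1] - t) < 0) + 1L
}

#' Count deliberate presses in one window
#'
#' Each press drives the filtered force above the threshold and back below
#' it, contributing two strict crossings; the press count is therefore half
#' the number of crossings. A window that ends mid-peak (odd crossing count)
#' leaves the trailing half-crossing uncounted here — stream decoding defers
#' it to the next window so no press is counted twice or lost.
#'
#' @param a numeric filtered force sequence, length >= 2.
#' @param threshold force threshold (from [calibrate_threshold()] or a bare
#'   number).
#' @return an object of class `press_count` with fields `S` (integer press
#'   count), `threshold`, `n_samples`, `crossing_indices`.
#' @examples
#' count_presses(c(1, 6, 1, 7, 1), 5)$S  # 2
#' @export
count_presses <- function(a, threshold) {
  if (length(a) < 2L) stop("sequence must have at least 2 samples")
  if (inherits(threshold, "press_calibration")) threshold <- threshold$threshold
  cross <- threshold_crossings(a, threshold)
  structure(list(S = length(cross) %/% 2L,
                 threshold = threshold,
                 n_samples = length(a),
                 crossing_indices = cross),
            class = "press_count")
}

#' @export
print.press_count <- function(x, ...) {
  cat("<press_count> S =", x$S, "presses over", x$n_samples,
      "samples (threshold", format(x$threshold, digits = 6), ")\n")
  invisible(x)
}

#' Decode presses window by window from a trace
#'
#' Filters the chosen channel, partitions the stream into consecutive
#' non-overlapping scan windows of `scan_time` seconds, and counts completed
#' presses in each. A press belongs to the window in which its falling
#' crossing occurs: a peak still above threshold at a window boundary is
#' carried into the next window rather than split, so summed window counts
#' equal the total press count. A final rising crossing with no matching
#' fall by end of stream is never counted.
#'
#' The first `window_length` samples are filter warm-up — the averaging
#' queue is still filling, so early filtered values carry nearly raw sensor
#' noise — and are excluded from crossing detection.
#'
#' @param trace a [force_trace()].
#' @param channel control channel name (normally `"hallux"`).
#' @param calibration a [calibrate_threshold()] result (or bare threshold).
#' @param scan_time window length b in seconds, > 0 (default 1.5); the
#'   shortest acquisition period, a trade-off between control latency and
#'   how many presses fit in one command cycle.
#' @param params a [filter_params()].
#' @return data frame of class `press_windows`: one row per window with
#'   `window`, `start_s`, `end_s`, `S`.
#' @export
stream_windows <- function(trace, channel, calibration,
                           scan_time = 1.5, params = filter_params()) {
  stopifnot(scan_time > 0)
  thr <- if (inherits(calibration, "press_calibration")) {
    calibration$threshold
  } else {
    as.numeric(calibration)
  }
  a <- filter_trace(trace, channel, params)
  fs <- trace$sampling_rate
  n_win <- max(2L, as.integer(round(scan_time * fs)))
  n <- length(a)
  warm <- min(params$window_length, n - 1L)
  cross <- threshold_crossings(a[warm:n], thr) + warm - 1L
  # crossings alternate rise/fall; a press completes at its fall (every
  # even-numbered crossing once alternation starts below threshold). A
  # stream already above threshold when decoding starts has a fall with no
  # matching rise: that run is not a decoded press, so its crossing is
  # dropped.
  if (a[warm] > thr && length(cross)) cross <- cross[-1]
  falls <- cross[seq_along(cross) %% 2L == 0L]
  starts <- seq.int(1L, n, by = n_win)
  ends <- pmin(starts + n_win - 1L, n)
  S <- vapply(seq_along(starts), function(w) {
    sum(falls >= starts[w] & falls <= ends[w])
  }, integer(1))
  structure(
    data.frame(window = seq_along(starts),
               start_s = trace$start_time + (starts - 1L) / fs,
               end_s = trace$start_time + ends / fs,
               S = S),
    class = c("press_windows", "data.frame"),
    threshold = thr, scan_time = scan_time, channel = channel
  )
}
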