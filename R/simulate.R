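#' Sensor channel specification
#'
#' Describes one force-sensing region of the smart insole: its resting load,
#' the amplitude of the periodic peak it shows during walking, the amplitude
#' of a deliberate press, and the sensor noise level. Forces are dimensionless
#' sensor counts on the 0--2500 scale of the insole's A/D converter.
#'
#' For the toe channels (`hallux`, `little_toe`) a deliberate press must be
#' larger than the walking peak — that amplitude separation is what makes
#' press decoding possible at all — so `press_peak_amplitude >
#' gait_peak_amplitude` is enforced for those regions.
#'
#' @param region one of `"hallux"`, `"little_toe"`, `"forefoot"`, `"heel"`.
#' @param baseline_force resting force (sensor counts), >= 0.
#' @param gait_peak_amplitude amplitude of the per-step peak while walking.
#' @param press_peak_amplitude amplitude added by a deliberate press.
#' @param noise_sd standard deviation of additive sensor noise.
#' @return an object of class `channel_spec`.
#' @seealso [default_channel_specs()], [generate_trace()]
#' @export
channel_spec <- function(region,
                         baseline_force = 100,
                         gait_peak_amplitude = 0,
                         press_peak_amplitude = 0,
                         noise_sd = 0) {
  region <- match.arg(region, c("hallux", "little_toe", "forefoot", "heel"))
  stopifnot(baseline_force >= 0, gait_peak_amplitude >= 0,
            press_peak_amplitude >= 0, noise_sd >= 0)
  if (region %in% c("hallux", "little_toe") &&
      press_peak_amplitude > 0 &&
      press_peak_amplitude <= gait_peak_amplitude) {
    stop("for toe channels press_peak_amplitude must exceed gait_peak_amplitude")
  }
  structure(
    list(region = region,
         baseline_force = baseline_force,
         gait_peak_amplitude = gait_peak_amplitude,
         press_peak_amplitude = press_peak_amplitude,
         noise_sd = noise_sd),
    class = "channel_spec"
  )
}

#' Default insole channel specifications
#'
#' One spec per foot region, on the nominal 0--2500 sensor-count scale:
#' hallux presses reach ~2000 counts while hallux walking peaks stay near
#' 500, so a threshold calibrated on press-free data separates the two.
#'
#' @param noise_sd sensor noise standard deviation shared by all channels.
#' @return named list of [channel_spec()] objects
#'   (`hallux`, `little_toe`, `forefoot`, `heel`).
#' @export
default_channel_specs <- function(noise_sd = 30) {
  list(
    hallux     = channel_spec("hallux",     baseline_force = 100,
                              gait_peak_amplitude = 500,
                              press_peak_amplitude = 2000,
                              noise_sd = noise_sd),
    little_toe = channel_spec("little_toe", baseline_force = 80,
                              gait_peak_amplitude = 400,
                              press_peak_amplitude = 1500,
                              noise_sd = noise_sd),
    forefoot   = channel_spec("forefoot",   baseline_force = 200,
                              gait_peak_amplitude = 1800,
                              noise_sd = noise_sd),
    heel       = channel_spec("heel",       baseline_force = 200,
                              gait_peak_amplitude = 2000,
                              noise_sd = noise_sd)
  )
}

#' Press schedule
#'
#' Deliberate toe presses to inject into a simulated trace. Events on the
#' same channel must not overlap.
#'
#' @param onset press onset times in seconds (>= 0).
#' @param duration press durations in seconds (> 0).
#' @param channel channel name for each event (recycled if length 1).
#' @return a `press_schedule` data frame with columns
#'   `onset`, `duration`, `channel`.
#' @export
press_schedule <- function(onset = numeric(), duration = numeric(),
                           channel = character()) {
  if (length(onset) == 0L) {
    duration <- numeric(); channel <- character()
  }
  if (length(onset) > 0 && length(channel) == 1L) {
    channel <- rep(channel, length(onset))
  }
  if (length(duration) == 1L && length(onset) > 1L) {
    duration <- rep(duration, length(onset))
  }
  stopifnot(length(onset) == length(duration),
            length(onset) == length(channel))
  if (length(onset)) {
    stopifnot(all(onset >= 0), all(duration > 0))
    for (ch in unique(channel)) {
      i <- channel == ch
      o <- order(onset[i])
      on <- onset[i][o]; du <- duration[i][o]
      if (length(on) > 1L && any(on[-1] < (on + du)[-length(on)])) {
        stop("overlapping press events on channel '", ch, "'")
      }
    }
  }
  structure(
    data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
               channel = as.character(channel),
               stringsAsFactors = FALSE),
    class = c("press_schedule", "data.frame")
  )
}

#' Gait specification
#'
#' The lower limbs have two states relevant to daily activities: rest
#' (standing/sitting) and movement (walking). Walking loads the heel and
#' forefoot channels with one force peak per step; standing leaves the toe
#' channels near their baselines.
#'
#' @param regime `"standing"` or `"walking"`.
#' @param cadence steps per second (walking only), > 0.
#' @param stance_fraction fraction of each step cycle with foot-ground
#'   contact, in (0, 1).
#' @return an object of class `gait_spec`.
#' @export
gait_spec <- function(regime = c("standing", "walking"),
                      cadence = 1.5, stance_fraction = 0.6) {
  regime <- match.arg(regime)
  stopifnot(stance_fraction > 0, stance_fraction < 1)
  if (regime == "walking") stopifnot(cadence > 0)
  structure(list(regime = regime, cadence = cadence,
                 stance_fraction = stance_fraction),
            class = "gait_spec")
}

#' Construct a force trace
#'
#' A uniformly sampled multi-channel contact-force time series. Channels are
#' held as a numeric matrix with one named column per sensor channel.
#'
#' @param channels numeric matrix, one column per channel (named).
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param start_time time of the first sample in seconds.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(channels, sampling_rate, start_time = 0) {
  channels <- as.matrix(channels)
  stopifnot(is.numeric(channels), sampling_rate > 0,
            !is.null(colnames(channels)), all(channels >= 0))
  structure(list(channels = channels,
                 sampling_rate = as.numeric(sampling_rate),
                 start_time = as.numeric(start_time)),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat("<force_trace> ", nrow(x$channels), " samples x ",
      ncol(x$channels), " channels @ ", x$sampling_rate, " Hz (",
      format(nrow(x$channels) / x$sampling_rate, digits = 4), " s)\n",
      sep = "")
  cat("  channels:", paste(colnames(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of a force trace
#'
#' @param trace a [force_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  trace$start_time + (seq_len(nrow(trace$channels)) - 1L) / trace$sampling_rate
}

#' Extract one channel of a force trace
#'
#' @param trace a [force_trace()].
#' @param channel channel (column) name.
#' @return numeric vector of force samples.
#' @export
trace_channel <- function(trace, channel) {
  stopifnot(inherits(trace, "force_trace"))
  if (!channel %in% colnames(trace$channels)) {
    stop("channel '", channel, "' not present in trace")
  }
  trace$channels[, channel]
}

# Raised-cosine press bump sampled at times tt: smooth, unimodal, zero at
# both ends, peak amplitude A at the centre of the press.
press_bump <- function(tt, onset, duration, amplitude) {
  u <- (tt - onset) / duration
  out <- numeric(length(tt))
  inside <- u >= 0 & u <= 1
  out[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  out
}

# Half-sine gait loading: one peak per step over the stance fraction of the
# cycle, zero during swing.
gait_wave <- function(tt, cadence, stance_fraction, amplitude) {
  phase <- (tt * cadence) %% 1
  out <- numeric(length(tt))
  st <- phase < stance_fraction
  out[st] <- amplitude * sin(pi * phase[st] / stance_fraction)
  out
}

#' Simulate a multi-channel insole force trace
#'
#' Builds each channel as baseline + gait loading + scheduled press bumps +
#' sensor noise. Walking places a half-sine force peak per step in every
#' loaded channel (large in heel/forefoot, smaller in the toes); standing
#' leaves channels at baseline. A press adds a smooth raised-cosine bump of
#' the channel's press amplitude. Noise is zero-mean Gaussian; forces are
#' clipped at zero since the sensor cannot report negative load.
#'
#' @param gait a [gait_spec()].
#' @param specs named list of [channel_spec()] objects; names become channel
#'   names.
#' @param presses a [press_schedule()]; every scheduled channel must appear
#'   in `specs`.
#' @param duration trace duration in seconds, > 0.
#' @param sampling_rate sampling rate in Hz, > 0 (default 100).
#' @param seed integer seed; identical seed and parameters give a bitwise
#'   identical trace. `NULL` leaves the RNG state alone.
#' @return a [force_trace()].
#' @examples
#' tr <- generate_trace(gait_spec("standing"),
#'                      presses = press_schedule(2, 0.25, "hallux"),
#'                      duration = 5, seed = 1)
#' tr
#' @export
generate_trace <- function(gait,
                           specs = default_channel_specs(),
                           presses = press_schedule(),
                           duration,
                           sampling_rate = 100,
                           seed = NULL) {
  stopifnot(inherits(gait, "gait_spec"), duration > 0, sampling_rate > 0)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, `[[`, "", "region")
  }
  bad <- setdiff(unique(presses$channel), names(specs))
  if (length(bad)) {
    stop("press schedule references unknown channel(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- floor(duration * sampling_rate)
  tt <- (seq_len(n) - 1L) / sampling_rate
  ch <- matrix(0, n, length(specs), dimnames = list(NULL, names(specs)))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    y <- rep(sp$baseline_force, n)
    if (gait$regime == "walking" && sp$gait_peak_amplitude > 0) {
      y <- y + gait_wave(tt, gait$cadence, gait$stance_fraction,
                         sp$gait_peak_amplitude)
    }
    ev <- presses[presses$channel == nm, , drop = FALSE]
    for (j in seq_len(nrow(ev))) {
      y <- y + press_bump(tt, ev$onset[j], ev$duration[j],
                          sp$press_peak_amplitude)
    }
    if (sp$noise_sd > 0) y <- y + stats::rnorm(n, 0, sp$noise_sd)
    ch[, nm] <- pmax(y, 0)
  }
  force_trace(ch, sampling_rate)
}

#' Write a force trace to delimited text
#'
#' Comma-separated with header `time_s,<channel>,...`; channel order and
#' names are preserved exactly (sensor labels such as `1#` are legal).
#'
#' @param trace a [force_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  df <- data.frame(time_s = trace_times(trace), trace$channels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a force trace from delimited text
#'
#' Inverse of [write_trace()]: expects a `time_s` column plus one numeric
#' column per channel; the sampling rate is recovered from the time column.
#'
#' @param path input file path.
#' @return a [force_trace()].
#' @export
read_trace <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("malformed trace file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(df) < 2L || names(df)[1] != "time_s") {
    stop("malformed trace file '", path,
         "': need a 'time_s' column and at least 2 rows")
  }
  if (!all(vapply(df, is.numeric, TRUE))) {
    stop("malformed trace file '", path, "': non-numeric values")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-12) {
    stop("malformed trace file '", path, "': time column not uniform")
  }
  force_trace(as.matrix(df[-1]), sampling_rate = 1 / stats::median(dt),
              start_time = df$time_s[1])
}
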