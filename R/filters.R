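#' Filter parameters
#'
#' Tuning for the two-stage smoother: a causal recursive (moving) average of
#' length `window_length`, followed by a scalar Kalman filter with state
#' model `x_k = F x_{k-1} + B u_{k-1} + w`, `z_k = H x_k + v`, where `w` has
#' variance `Q` and `v` has variance `R`.
#'
#' The averaging window is conventionally 40--60 samples; the default is the
#' midpoint, 50. The Kalman model defaults to a random-walk force level
#' (`F = 1`, `B = 0`, `H = 1`): the smoothed contact force varies slowly and
#' no richer dynamics are warranted.
#'
#' @param window_length moving-average queue length N in samples, >= 1.
#' @param F state-transition scalar.
#' @param B control-input scalar (input u is 0 throughout this package).
#' @param H observation scalar.
#' @param Q process-noise variance, >= 0.
#' @param R measurement-noise variance, > 0.
#' @param x0 initial state; `NULL` means "first averaged sample" when a whole
#'   sequence is filtered.
#' @param P0 initial error covariance, >= 0.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(window_length = 50, F = 1, B = 0, H = 1,
                          Q = 1e-2, R = 1, x0 = NULL, P0 = 1) {
  stopifnot(window_length >= 1, Q >= 0, P0 >= 0)
  if (R <= 0) stop("measurement-noise variance R must be > 0")
  structure(list(window_length = as.integer(window_length),
                 F = F, B = B, H = H, Q = Q, R = R, x0 = x0, P0 = P0),
            class = "filter_params")
}

#' Kalman filter state
#'
#' Scalar posterior/prior state and error covariance after one
#' predict-update cycle.
#'
#' @param x_est posterior state estimate.
#' @param P posterior error covariance, >= 0.
#' @param x_pred prior (predicted) state.
#' @param P_pred prior error covariance.
#' @return an object of class `kalman_state`.
#' @export
kalman_state <- function(x_est, P, x_pred = x_est, P_pred = P) {
  stopifnot(P >= 0)
  structure(list(x_est = x_est, P = P, x_pred = x_pred, P_pred = P_pred),
            class = "kalman_state")
}

#' Causal recursive (moving) average
#'
#' Element `k` of the output is the arithmetic mean of the most recent
#' `min(k, N)` samples up to and including sample `k`; during warm-up
#' (`k < N`) the available prefix is averaged rather than padding with
#' fabricated pre-stream data.
#'
#' @param x numeric force sequence, non-empty.
#' @param window_length queue length N in samples, >= 1.
#' @return numeric vector the same length as `x`.
#' @examples
#' recursive_average(c(0, 10, 20, 30), 2)  # 0, 5, 15, 25
#' @export
recursive_average <- function(x, window_length) {
  if (length(x) == 0L) stop("empty input sequence")
  n <- as.integer(window_length)
  if (is.na(n) || n < 1L) stop("window_length must be >= 1")
  if (n == 1L) return(x)
  len <- length(x)
  cs <- cumsum(x)
  k <- seq_len(len)
  out <- cs / k
  if (n < len) {
    tail_idx <- (n + 1L):len
    out[tail_idx] <- (cs[tail_idx] - cs[tail_idx - n]) / n
  }
  out
}

#' One scalar Kalman predict-update step
#'
#' Predict: `x_pred = F x_est + B u`, `P_pred = F^2 P + Q`. Update with
#' gain `K = P_pred H / (H^2 P_pred + R)`:
#' `x_est' = x_pred + K (z - H x_pred)`, `P' = (1 - K H) P_pred`.
#' The update never increases uncertainty: `P' <= P_pred`.
#'
#' @param state a [kalman_state()].
#' @param z scalar observation.
#' @param u control input applied over the previous interval (default 0).
#' @param params a [filter_params()].
#' @return the new [kalman_state()].
#' @export
kalman_step <- function(state, z, u = 0, params = filter_params()) {
  stopifnot(inherits(state, "kalman_state"), inherits(params, "filter_params"))
  x_pred <- params$F * state$x_est + params$B * u
  P_pred <- params$F^2 * state$P + params$Q
  K <- P_pred * params$H / (params$H^2 * P_pred + params$R)
  x_est <- x_pred + K * (z - params$H * x_pred)
  P <- (1 - K * params$H) * P_pred
  kalman_state(x_est = x_est, P = P, x_pred = x_pred, P_pred = P_pred)
}

#' Kalman sweep over a sequence
#'
#' Runs [kalman_step()] along `x` with zero control input, starting from
#' `params$x0` (or the first sample when `x0` is `NULL`) and covariance
#' `params$P0`.
#'
#' @param x numeric sequence, non-empty.
#' @param params a [filter_params()].
#' @return numeric vector of posterior estimates, same length as `x`.
#' @export
kalman_filter <- function(x, params = filter_params()) {
  if (length(x) == 0L) stop("empty input sequence")
  x0 <- if (is.null(params$x0)) x[1] else params$x0
  st <- kalman_state(x_est = x0, P = params$P0)
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    st <- kalman_step(st, x[k], u = 0, params = params)
    out[k] <- st$x_est
  }
  out
}

#' Filter one channel of a trace
#'
#' The full preprocessing chain applied to raw insole data: recursive
#' averaging to knock down sensor noise, then the scalar Kalman sweep to
#' suppress what remains. The output has the same length as the channel; the
#' smoothing buys noise reduction at the cost of some delay, which is
#' acceptable because users press ahead of the grasp they intend.
#'
#' @param trace a [force_trace()].
#' @param channel channel name (e.g. `"hallux"`).
#' @param params a [filter_params()].
#' @return numeric vector of filtered force values.
#' @export
filter_trace <- function(trace, channel, params = filter_params()) {
  y <- trace_channel(trace, channel)
  kalman_filter(recursive_average(y, params$window_length), params)
}
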