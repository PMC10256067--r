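#' Opening-time calibration dataset
#'
#' Pairs of interfinger distance `l` (mm, 0--100) and opening-time ratio
#' `d = t / t_A`, where `t` is the time the hand's open line must be held
#' high to open the fingers to `l` from fully closed and `t_A` is the
#' full-open time. The hand has no position feedback, so this timed-opening
#' table is the only posture calibration available.
#'
#' @param distance interfinger distances in mm, each in \[0, 100\].
#' @param time_ratio opening-time ratios, each in (0, 1\].
#' @param full_open_time full-open time t_A in seconds, > 0.
#' @return an object of class `posture_dataset`.
#' @export
posture_dataset <- function(distance, time_ratio, full_open_time = 2) {
  stopifnot(length(distance) == length(time_ratio), length(distance) >= 2)
  if (any(distance < 0 | distance > 100)) {
    stop("interfinger distances must lie in [0, 100] mm")
  }
  if (any(time_ratio <= 0 | time_ratio > 1)) {
    stop("time ratios must lie in (0, 1]")
  }
  if (full_open_time <= 0) stop("full_open_time must be > 0")
  structure(list(distance = as.numeric(distance),
                 time_ratio = as.numeric(time_ratio),
                 full_open_time = as.numeric(full_open_time)),
            class = "posture_dataset")
}

#' @export
print.posture_dataset <- function(x, ...) {
  cat("<posture_dataset>", length(x$distance), "distance/time-ratio pairs,",
      "t_A =", x$full_open_time, "s\n")
  invisible(x)
}

#' The packaged opening-time measurements
#'
#' The bench calibration of the three-finger assistive hand: 23 pairs of
#' interfinger distance (mm) and opening-time ratio, measured by timing the
#' open command from fully closed and repeating across the 0--100 mm span.
#' Note the nonzero intercept (ratio 0.25 at 0 mm): the opening line must be
#' held for a quarter of the full-open time before the fingers separate at
#' all — motor dead travel.
#'
#' @param full_open_time full-open time t_A in seconds to attach (default 2).
#' @return a [posture_dataset()].
#' @export
hand_opening_times <- function(full_open_time = 2) {
  path <- system.file("extdata", "opening_times.csv", package = "halluxgrip",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  posture_dataset(df$size_mm, df$time_ratio, full_open_time)
}

#' Opening-time ratio
#'
#' @param t opening time in seconds.
#' @param t_full full-open time t_A in seconds, > 0.
#' @return `t / t_full`.
#' @export
time_ratio <- function(t, t_full) {
  if (any(t_full <= 0)) stop("full-open time must be > 0")
  t / t_full
}

# Evaluate the model's transformed abscissa.
posture_abscissa <- function(model, l) {
  (l - unname(model$transform["shift"])) / unname(model$transform["scale"])
}

# Vandermonde design matrix [1, lam, lam^2, ..., lam^M].
posture_design <- function(lambda, order) {
  outer(lambda, 0:order, `^`)
}

#' Fit the distance-to-time-ratio polynomial
#'
#' Least squares of time ratio on a degree-`order` polynomial of interfinger
#' distance, the calibration that lets timed open commands hit a target
#' posture. The abscissa is centred and scaled (training mean/sd) before
#' powers are taken, purely for numerical conditioning: the degree-M
#' polynomial space is closed under affine substitution, so SSE and
#' R-squared do not depend on this transform. Coefficients solve the normal
#' equations (computed stably by QR).
#'
#' @param data a [posture_dataset()].
#' @param order polynomial degree M, >= 1 and < number of observations.
#' @return an object of class `posture_model` with fields `order`,
#'   `intercept`, `coefficients` (w_1..w_M on the transformed abscissa),
#'   `transform` (`shift`, `scale`), `sse`, `r_squared`, `full_open_time`,
#'   and the training `data`.
#' @export
fit_polynomial <- function(data, order) {
  stopifnot(inherits(data, "posture_dataset"))
  order <- as.integer(order)
  n <- length(data$distance)
  if (is.na(order) || order < 1L) stop("order must be >= 1")
  if (order >= n) stop("order must be less than the number of observations")
  shift <- mean(data$distance)
  scale <- stats::sd(data$distance)
  if (scale == 0) stop("degenerate dataset: all distances identical")
  lambda <- (data$distance - shift) / scale
  L <- posture_design(lambda, order)
  qr_L <- qr(L)
  if (qr_L$rank < ncol(L)) stop("rank-deficient design matrix")
  w <- qr.coef(qr_L, data$time_ratio)
  fitted <- drop(L %*% w)
  resid <- data$time_ratio - fitted
  sse <- sum(resid^2)
  tss <- sum((data$time_ratio - mean(data$time_ratio))^2)
  structure(list(order = order,
                 intercept = w[1],
                 coefficients = w[-1],
                 transform = c(shift = shift, scale = scale),
                 sse = sse,
                 r_squared = 1 - sse / tss,
                 full_open_time = data$full_open_time,
                 data = data),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat("<posture_model> degree", x$order,
      " SSE =", format(x$sse, digits = 4),
      " R^2 =", format(x$r_squared, digits = 6), "\n")
  cat("  abscissa: (l -", format(x$transform["shift"], digits = 4), ") /",
      format(x$transform["scale"], digits = 4), "\n")
  invisible(x)
}

#' Choose the polynomial order from SSE diagnostics
#'
#' Fits degrees 1..`max_order` and picks the elbow of the SSE curve: the
#' largest degree whose SSE still improves on the previous degree by at
#' least `tol` (relative). Once the relative improvement falls below `tol`,
#' extra degrees buy only computational cost. A fit whose SSE is already
#' negligible against the total sum of squares stops the search immediately
#' (noise-free data would otherwise make the relative improvement
#' meaningless).
#'
#' @param data a [posture_dataset()].
#' @param max_order largest degree to try, >= 1 and < number of
#'   observations.
#' @param tol minimum relative SSE improvement to justify a higher degree
#'   (default 0.2).
#' @return list with `order` (chosen degree) and `diagnostics`, a data frame
#'   of `order`, `sse`, `r_squared`.
#' @export
select_order <- function(data, max_order = 6, tol = 0.2) {
  stopifnot(inherits(data, "posture_dataset"))
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 1L) stop("max_order must be >= 1")
  fits <- lapply(seq_len(max_order), function(m) fit_polynomial(data, m))
  sse <- vapply(fits, `[[`, 0, "sse")
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  tss <- sum((data$time_ratio - mean(data$time_ratio))^2)
  chosen <- max_order
  for (m in seq_len(max_order)) {
    if (sse[m] <= 1e-12 * tss) { chosen <- m; break }
    if (m > 1L && (sse[m - 1] - sse[m]) / sse[m - 1] < tol) {
      chosen <- m - 1L
      break
    }
  }
  list(order = chosen,
       diagnostics = data.frame(order = seq_len(max_order),
                                sse = sse, r_squared = r2))
}

#' Predict the opening-time ratio for a target distance
#'
#' Evaluates the fitted polynomial at interfinger distance `l`, clamped to
#' \[0, 1\] (a ratio outside that range is physically meaningless).
#'
#' @param model a [posture_model()].
#' @param l target interfinger distance(s) in mm, each in \[0, 100\].
#' @return predicted time ratio(s).
#' @export
predict_ratio <- function(model, l) {
  stopifnot(inherits(model, "posture_model"))
  if (any(l < 0 | l > 100)) {
    stop("target distance outside the hand's 0-100 mm span")
  }
  lambda <- posture_abscissa(model, l)
  d <- drop(posture_design(lambda, model$order) %*%
              c(model$intercept, model$coefficients))
  pmin(pmax(d, 0), 1)
}

#' Opening time for a target distance
#'
#' The duration the open line must be held from fully closed to reach
#' interfinger distance `l`: `t_open = d(l) * t_A`.
#'
#' @param model a [posture_model()].
#' @param l target interfinger distance(s) in mm.
#' @param t_full full-open time t_A in seconds, > 0 (default: the training
#'   dataset's).
#' @return opening time(s) in seconds.
#' @export
opening_time <- function(model, l, t_full = model$full_open_time) {
  if (any(t_full <= 0)) stop("full-open time must be > 0")
  predict_ratio(model, l) * t_full
}
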