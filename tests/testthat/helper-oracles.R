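# Independent brute-force oracles the implementation is checked against.

# Windowed mean computed directly from the definition.
brute_moving_average <- function(x, n) {
  vapply(seq_along(x), function(k) mean(x[max(1, k - n + 1):k]), 0)
}

# Number of maximal runs of samples strictly above t, for sequences that
# start and end below t.
brute_peak_runs <- function(a, t) {
  above <- a > t
  sum(above & !c(FALSE, above[-length(above)]))
}

# Count strict interior local maxima above a floor.
brute_local_maxima <- function(y, floor = -Inf) {
  n <- length(y)
  i <- 2:(n - 1)
  sum(y[i] > y[i - 1] & y[i] > y[i + 1] & y[i] > floor)
}

table5_distance <- c(100, 99.8, 97.31, 94.74, 94.01, 88.71, 83.62, 80.19,
                     77.49, 74.63, 70, 65, 60, 53.68, 45.8, 40.74, 33.14,
                     30.36, 25.14, 18.59, 11.54, 5.46, 0)
table5_ratio <- c(1, 0.95, 0.93, 0.91, 0.9, 0.85, 0.8, 0.78, 0.75, 0.73,
                  0.7, 0.65, 0.6, 0.55, 0.5, 0.45, 0.4, 0.37, 0.33, 0.3,
                  0.27, 0.26, 0.25)
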