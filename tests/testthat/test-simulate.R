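noiseless_specs <- function() {
  list(hallux = channel_spec("hallux", baseline_force = 100,
                             gait_peak_amplitude = 500,
                             press_peak_amplitude = 2000, noise_sd = 0),
       heel = channel_spec("heel", baseline_force = 200,
                           gait_peak_amplitude = 2000, noise_sd = 0))
}

test_that("noiseless standing trace sits at baseline and presses add clean bumps", {
  tr <- generate_trace(gait_spec("standing"), noiseless_specs(),
                       duration = 5, seed = 1)
  expect_true(all(trace_channel(tr, "hallux") == 100))

  tr2 <- generate_trace(gait_spec("standing"), noiseless_specs(),
                        presses = press_schedule(2, 0.5, "hallux"),
                        duration = 5, seed = 1)
  h <- trace_channel(tr2, "hallux")
  expect_equal(max(h), 100 + 2000, tolerance = 1e-8)
  # bump is confined to the scheduled interval and unimodal
  tt <- trace_times(tr2)
  expect_true(all(h[tt < 2 | tt > 2.5] == 100))
  expect_equal(brute_local_maxima(h, floor = 100), 1)
})

test_that("walking places one gait peak per step at the stated cadence", {
  tr <- generate_trace(gait_spec("walking", cadence = 1.5),
                       noiseless_specs(), duration = 10, seed = 1)
  heel <- trace_channel(tr, "heel")
  expect_equal(brute_local_maxima(heel, floor = 200), 15)
  # toe peaks present but smaller than a press
  trh <- generate_trace(gait_spec("walking", cadence = 1.5),
                        noiseless_specs(),
                        presses = press_schedule(4.2, 0.3, "hallux"),
                        duration = 10, seed = 1)
  h <- trace_channel(trh, "hallux")
  walking_only <- trace_channel(tr, "hallux")
  expect_gt(max(h), max(walking_only))
})

test_that("identical seed gives a bitwise-identical trace", {
  a <- generate_trace(gait_spec("walking"), duration = 4, seed = 42)
  b <- generate_trace(gait_spec("walking"), duration = 4, seed = 42)
  expect_identical(a, b)
  c <- generate_trace(gait_spec("walking"), duration = 4, seed = 43)
  expect_false(identical(a$channels, c$channels))
})

test_that("noise obeys the requested standard deviation", {
  sd0 <- 30
  clean <- generate_trace(gait_spec("standing"),
                          list(hallux = channel_spec("hallux", 200,
                                                     press_peak_amplitude = 2000,
                                                     noise_sd = 0)),
                          duration = 100, seed = 5)
  noisy <- generate_trace(gait_spec("standing"),
                          list(hallux = channel_spec("hallux", 200,
                                                     press_peak_amplitude = 2000,
                                                     noise_sd = sd0)),
                          duration = 100, seed = 5)
  dv <- var(trace_channel(noisy, "hallux") - trace_channel(clean, "hallux"))
  expect_lt(abs(dv - sd0^2) / sd0^2, 0.10)
})

test_that("invalid simulator inputs are rejected", {
  expect_error(generate_trace(gait_spec("standing"), noiseless_specs(),
                              presses = press_schedule(1, 0.2, "arch"),
                              duration = 5),
               "unknown channel")
  expect_error(generate_trace(gait_spec("standing"), noiseless_specs(),
                              duration = -1))
  expect_error(press_schedule(c(1, 1.1), c(0.5, 0.2), "hallux"),
               "overlapping")
  expect_error(channel_spec("hallux", gait_peak_amplitude = 500,
                            press_peak_amplitude = 400),
               "must exceed")
  expect_error(gait_spec("walking", cadence = 0))
})

test_that("trace files round-trip and preserve arbitrary channel labels", {
  tr <- generate_trace(gait_spec("walking"), duration = 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$channels, tr$channels, tolerance = 1e-12)
  expect_equal(back$sampling_rate, tr$sampling_rate, tolerance = 1e-9)

  # eight sensor labels in insole numbering order
  m <- matrix(runif(8 * 50, 0, 10), 50, 8,
              dimnames = list(NULL, paste0(1:8, "#")))
  tr8 <- force_trace(m, sampling_rate = 100)
  write_trace(tr8, path)
  expect_identical(colnames(read_trace(path)$channels), paste0(1:8, "#"))
})

test_that("malformed trace files are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  expect_error(read_trace(path), "malformed")
  writeLines(c("time_s,ch1", "0,1", "0.01,x"), path)
  expect_error(read_trace(path), "malformed")
  writeLines(c("time_s,ch1", "0,1", "0.5,2", "0.6,3"), path)
  expect_error(read_trace(path), "not uniform")
})
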