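model <- fit_polynomial(hand_opening_times(), 4)

test_that("press counts map to the five-level posture code", {
  map <- distance_level_map()
  closed <- hand_state(0)
  open <- hand_state(50)
  expect_equal(map_presses(1, closed, map), 25)
  expect_equal(map_presses(2, closed, map), 50)
  expect_equal(map_presses(3, closed, map), 75)
  expect_equal(map_presses(4, closed, map), 100)
  expect_equal(map_presses(7, closed, map), 100)  # saturates at full open
  expect_equal(map_presses(0, open, map), 0)      # no press while open closes
  expect_true(is.na(map_presses(0, closed, map))) # no press while closed: no-op
  expect_error(distance_level_map(c(`1` = 30, `2` = 20, `3` = 75, `4` = 100)))
  expect_error(distance_level_map(c(`1` = 25, `2` = 50)), "100 mm")
})

test_that("commands encode direction on the two lines with timed durations", {
  st <- hand_state(0)
  hold <- plan_command(st, 0, model)
  expect_identical(c(hold$line_a, hold$line_b), c("low", "low"))
  expect_equal(hold$duration, 0)

  open <- plan_command(st, 100, model, t_full = 2)
  expect_identical(c(open$line_a, open$line_b), c("high", "low"))
  d_span <- predict_ratio(model, 100) - predict_ratio(model, 0)
  expect_equal(open$duration, 2 * d_span, tolerance = 0.01)

  close <- plan_command(hand_state(100), 0, model)
  expect_identical(c(close$line_a, close$line_b), c("low", "high"))
  expect_gt(close$duration, 0)
  expect_error(plan_command(st, 140, model), "0-100")
})

test_that("the simulated plant inverts the timing calibration", {
  st <- hand_state(0)
  hold <- plan_command(st, 0, model)
  expect_identical(step_plant(st, hold, model), st)

  cmd <- plan_command(st, 75, model)
  after <- step_plant(st, cmd, model)
  expect_lt(abs(after$openness - 75), 2)

  # holding the open line for the whole full-open time saturates the hand
  full <- structure(list(line_a = "high", line_b = "low", duration = 2),
                    class = "control_command")
  expect_equal(step_plant(st, full, model, t_full = 2)$openness, 100)

  bad <- structure(list(line_a = "high", line_b = "high", duration = 1),
                   class = "control_command")
  expect_error(step_plant(st, bad, model), "both")
})

test_that("the drink-water scenario yields two presses, two openings, two closures", {
  tr <- scenario_trace("drink_water", seed = 3)
  base <- generate_trace(gait_spec("standing"), duration = 3, seed = 100)
  cal <- calibrate_threshold(filter_trace(base, "hallux"), 1.1)
  log <- run_closed_loop(tr, cal, model)
  expect_equal(sum(attr(log, "windows")$S), 2L)
  expect_equal(sum(log$line_a == "high"), 2L)
  expect_equal(sum(log$line_b == "high"), 2L)
  expect_equal(attr(log, "final_state")$openness, 0)
})

test_that("a press-free trace leaves the hand closed with an empty log", {
  quiet <- generate_trace(gait_spec("standing"), duration = 8, seed = 15)
  base <- generate_trace(gait_spec("standing"), duration = 3, seed = 16)
  cal <- calibrate_threshold(filter_trace(base, "hallux"), 1.1)
  log <- run_closed_loop(quiet, cal, model)
  expect_equal(nrow(log), 0L)
  expect_equal(attr(log, "final_state")$openness, 0)
})

test_that("press patterns across windows command the expected level sequence", {
  # windows of 4 s: 1 press | none | 3 presses | none
  onsets <- c(1.0, 8.2, 9.6, 11.0)
  tr <- generate_trace(gait_spec("standing"),
                       presses = press_schedule(onsets, 0.25, "hallux"),
                       duration = 16, seed = 18)
  base <- generate_trace(gait_spec("standing"), duration = 3, seed = 19)
  cal <- calibrate_threshold(filter_trace(base, "hallux"), 1.1)
  log <- run_closed_loop(tr, cal, model, scan_time = 4)
  expect_equal(log$target_mm, c(25, 0, 75, 0))
})

test_that("closed-loop control is deterministic, safe, and level-accurate", {
  n_bad_lines <- 0L
  worst_err <- 0
  for (seed in 1:200) {
    name <- c("drink_water", "tie_shoelaces", "take_off_coat")[seed %% 3 + 1]
    tr <- scenario_trace(name, seed = seed)
    base <- generate_trace(gait_spec("standing"), duration = 3,
                           seed = seed + 500)
    cal <- calibrate_threshold(filter_trace(base, "hallux"), 1.1)
    log <- run_closed_loop(tr, cal, model)
    n_bad_lines <- n_bad_lines +
      sum(log$line_a == "high" & log$line_b == "high")
    opens <- log[log$line_a == "high", ]
    if (nrow(opens)) {
      worst_err <- max(worst_err, abs(opens$openness_mm - opens$target_mm))
    }
    if (seed <= 10) {
      expect_identical(run_closed_loop(tr, cal, model), log)
    }
  }
  expect_equal(n_bad_lines, 0L)  # the undefined high/high row never appears
  expect_lt(worst_err, 2)        # achieved openness within 2 mm of command
})
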