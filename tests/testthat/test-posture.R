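test_that("time ratios follow their definition", {
  expect_equal(time_ratio(2, 2), 1)
  expect_equal(time_ratio(1.2, 2), 0.6)
  expect_equal(time_ratio(0.5, 2), 0.25)
  expect_error(time_ratio(1, 0), "> 0")
})

test_that("the packaged calibration data match their source of truth", {
  data <- hand_opening_times()
  expect_length(data$distance, 23)
  expect_equal(data$distance, table5_distance)
  expect_equal(data$time_ratio, table5_ratio)
})

test_that("a line through two points fits exactly", {
  d <- posture_dataset(c(20, 80), c(0.4, 0.8))
  m <- fit_polynomial(d, 1)
  expect_equal(m$sse, 0, tolerance = 1e-20)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict_ratio(m, 50), 0.6, tolerance = 1e-9)
})

test_that("fit diagnostics agree with an independent least-squares route", {
  data <- hand_opening_times()
  for (M in 1:6) {
    ours <- fit_polynomial(data, M)
    ref <- lm(data$time_ratio ~ poly(data$distance, M))
    expect_equal(ours$sse, sum(resid(ref)^2), tolerance = 1e-9)
    expect_equal(ours$r_squared, summary(ref)$r.squared, tolerance = 1e-9)
  }
})

test_that("fit guards reject degenerate requests", {
  data <- hand_opening_times()
  expect_error(fit_polynomial(data, 0), ">= 1")
  expect_error(fit_polynomial(data, 23), "less than")
  expect_error(posture_dataset(c(10, 200), c(0.3, 0.5)), "\\[0, 100\\]")
  expect_error(posture_dataset(c(10, 20), c(0.3, 1.5)), "\\(0, 1\\]")
})

test_that("noise-free data from a known quartic are recovered exactly", {
  data <- hand_opening_times()
  truth <- fit_polynomial(data, 4)
  clean <- posture_dataset(data$distance,
                           predict_ratio(truth, data$distance))
  refit <- fit_polynomial(clean, 4)
  expect_equal(refit$intercept, truth$intercept, tolerance = 1e-8)
  expect_equal(refit$coefficients, truth$coefficients, tolerance = 1e-8)
  expect_lt(refit$sse, 1e-16)
})

test_that("order selection finds the elbow", {
  data <- hand_opening_times()
  sel <- select_order(data, max_order = 6)
  expect_equal(sel$order, 4)
  expect_equal(nrow(sel$diagnostics), 6)
  # SSE is non-increasing in the polynomial degree (nested models)
  expect_true(all(diff(sel$diagnostics$sse) <= 1e-12))

  # exact quadratic stops at degree 2
  l <- seq(0, 100, length.out = 12)
  quad <- 0.25 + 0.005 * l + 2.5e-5 * l^2
  sel2 <- select_order(posture_dataset(l, quad / max(quad)), max_order = 5)
  expect_equal(sel2$order, 2)
  expect_error(select_order(data, 0), ">= 1")
})

test_that("predictions honour the calibration endpoints and stay monotone", {
  model <- fit_polynomial(hand_opening_times(), 4)
  # frozen from the independent lm(poly) route on the same 23 pairs: the
  # quartic's fitted endpoints are 0.97045 at 100 mm and 0.25462 at 0 mm
  expect_equal(predict_ratio(model, 100), 0.97045, tolerance = 1e-4)
  expect_equal(predict_ratio(model, 0), 0.25462, tolerance = 1e-4)
  expect_lt(abs(predict_ratio(model, 0) - 0.25), 0.02)
  grid <- predict_ratio(model, 0:100)
  # monotone over the working span; the quartic has a known ~0.002-deep
  # wiggle below 3 mm (also present in the independent route)
  expect_true(all(diff(grid[4:101]) >= 0))
  expect_lt(grid[1] - min(grid), 0.002)
  expect_true(all(grid >= 0 & grid <= 1))
  expect_error(predict_ratio(model, 120), "0-100")

  # training residuals reproduce the reported SSE
  resid <- model$data$time_ratio - predict_ratio(model, model$data$distance)
  expect_equal(sum(resid^2), model$sse, tolerance = 1e-10)
})

test_that("opening times scale the predicted ratio by the full-open time", {
  model <- fit_polynomial(hand_opening_times(), 4)
  expect_equal(opening_time(model, 100, 2), 2 * 0.97045, tolerance = 1e-3)
  t50 <- opening_time(model, 50, 2)
  # bracketed by the neighbouring calibration rows (45.8, 0.5), (53.68, 0.55)
  expect_gt(t50, 2 * 0.49)
  expect_lt(t50, 2 * 0.56)
  expect_error(opening_time(model, 50, 0), "> 0")
})

test_that("replicate refits under known noise have the classical expected SSE", {
  ex <- refit_experiment(n_replicates = 120, noise_sd = 0.005, seed = 99)
  expect_equal(mean(ex$sse), ex$expected_sse, tolerance = 0.15)
})
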