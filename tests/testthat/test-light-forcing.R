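test_that("waveforms are periodic and confined to the light phase", {
  profs <- list(
    light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6),
    light_profile("adaptation", x_max = 2, t_s = 1, t_d = 11),
    light_profile("slow_response", x_max = 0.75, t_r = 9, t_s = 3),
    light_profile("square", x_max = 0.75))
  set.seed(11)
  ts <- runif(40, -50, 100)
  for (pr in profs) {
    expect_equal(light_value(pr, ts), light_value(pr, ts + pr$period),
                 tolerance = 1e-12)
    u <- ts %% pr$period
    dark <- u >= pr$photoperiod
    x <- light_value(pr, ts)
    expect_true(all(x[dark] == 0))
    expect_true(all(x >= 0 & x <= pr$x_max + 1e-12))
  }
})

test_that("piecewise values match the closed form", {
  pr <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  # mid-plateau, mid-decay, dark
  expect_equal(light_value(pr, c(3, 9, 15)), c(1.5, 0.75, 0))
  # square wave: plateau over the whole light phase, half-open at lights-off
  sq <- light_profile("square", x_max = 2)
  expect_equal(light_value(sq, c(0, 11.99)), c(2, 2))
  expect_equal(light_value(sq, c(12, 23.99)), c(0, 0))
  # slow response ramps then plateaus to lights-off
  sl <- light_profile("slow_response", x_max = 0.75, t_r = 9, t_s = 3)
  expect_equal(light_value(sl, c(4.5, 10, 12)), c(0.375, 0.75, 0))
})

test_that("the integral over one cycle matches the closed form", {
  ad <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  num <- stats::integrate(function(t) light_value(ad, t), 0, 24,
                          subdivisions = 2000)$value
  expect_equal(num, 1.5 * (6 + 6 / 2), tolerance = 1e-4)
  sl <- light_profile("slow_response", x_max = 0.75, t_r = 9, t_s = 3)
  num2 <- stats::integrate(function(t) light_value(sl, t), 0, 24,
                           subdivisions = 2000)$value
  expect_equal(num2, 0.75 * (3 + 9 / 2), tolerance = 1e-4)
})

test_that("constructor rejects waveforms that do not fit the photoperiod", {
  expect_error(light_profile("adaptation", x_max = 1, t_s = 8, t_d = 6),
               "T_s \\+ T_d <= photoperiod")
  expect_error(light_profile("slow_response", x_max = 1, t_r = 5, t_s = 3),
               "T_r \\+ T_s = photoperiod")
  expect_error(light_pulse("adaptation", x_max = 1, t_s = 10, t_d = 6,
                           duration = 12), "does not fit")
  expect_error(light_profile("adaptation", x_max = -1, t_s = 6, t_d = 6),
               "x_max")
})

test_that("single pulses vanish outside their window and match the waveform inside", {
  rect <- light_pulse("square", x_max = 0.75)
  expect_equal(light_value(rect, c(-1, 6, 13)), c(0, 0.75, 0))
  ad <- light_pulse("adaptation", x_max = 1, t_s = 3, t_d = 9)
  expect_equal(light_value(ad, 7.5), 0.5)  # midpoint of the linear decay
  expect_equal(light_value(ad, c(-0.01, 12)), c(0, 0))
})

test_that("shrinking the decay or rise converges to the plateau-only waveform", {
  sq <- light_profile("square", x_max = 1)
  ts <- setdiff(seq(0.25, 23.75, by = 0.5), 12)  # avoid the breakpoint itself
  ad <- light_profile("adaptation", x_max = 1, t_s = 12 - 1e-6, t_d = 1e-6)
  expect_lt(max(abs(light_value(ad, ts) - light_value(sq, ts))), 1e-5)
  sl <- light_profile("slow_response", x_max = 1, t_r = 1e-6, t_s = 12 - 1e-6)
  expect_lt(max(abs(light_value(sl, ts) - light_value(sq, ts))), 1e-5)
})

test_that("profiles round-trip through config serialization", {
  pr <- light_profile("slow_response", x_max = 0.75, t_r = 9, t_s = 3)
  pr2 <- profile_from_config(profile_to_config(pr))
  expect_equal(pr2, pr)
})
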