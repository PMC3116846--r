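test_that("observations are deterministic given the seed", {
  des <- sampling_design("LD", noise_cv = 0.1, seed = 42)
  p <- clock_params()
  prof <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  s1 <- generate_observations(p, prof, des)
  s2 <- generate_observations(p, prof, des)
  expect_identical(s1$mrna_rel, s2$mrna_rel)
  des2 <- sampling_design("LD", noise_cv = 0.1, seed = 43)
  s3 <- generate_observations(p, prof, des2)
  expect_false(identical(s1$mrna_rel, s3$mrna_rel))
  # and the generator does not disturb the session RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_observations(p, prof, des)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless samples equal the dense truth at the sample times", {
  des <- sampling_design("LD", noise_cv = 0)
  prof <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  ser <- generate_observations(clock_params(), prof, des, relative = FALSE)
  truth <- attr(ser, "truth")
  m_t <- approx(truth$time_h, truth$M_nM, xout = ser$time_h)$y
  expect_equal(ser$mrna_rel, m_t, tolerance = 1e-9)
  p_t <- approx(truth$time_h, truth$Pt_nM, xout = ser$time_h)$y
  expect_equal(ser$protein_total_rel, p_t, tolerance = 1e-9)
})

test_that("the multiplicative noise has the designed coefficient of variation", {
  des <- sampling_design("LD", cycle_period = 24,
                         sample_times = seq(0.1, 239.9, length.out = 1000),
                         noise_cv = 0.1, seed = 7)
  prof <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  ser <- generate_observations(clock_params(), prof, des, relative = FALSE)
  truth <- attr(ser, "truth")
  ratio <- ser$mrna_rel / approx(truth$time_h, truth$M_nM, xout = ser$time_h)$y
  expect_gt(sd(ratio) / mean(ratio), 0.08)
  expect_lt(sd(ratio) / mean(ratio), 0.12)
})

test_that("preset truths have the documented response timing and are entrained", {
  frq <- clock_scenario("neurospora_frq_LD", noise_cv = 0)
  t_frq <- attr(frq$series, "truth")
  peak <- t_frq$time_h[which.max(t_frq$X)] %% 24
  expect_lte(peak, 1)  # maximal within 1 h of lights-on
  per1 <- clock_scenario("mouse_per1_LD", noise_cv = 0)
  t_p1 <- attr(per1$series, "truth")
  # plateau (maximal response) extends to 4 h after lights-on, then decays
  xs <- approx(t_p1$time_h, t_p1$X, xout = c(3.9, 4.1, 8))$y
  expect_equal(xs[1], max(t_p1$X), tolerance = 1e-9)
  expect_lt(xs[2], xs[1])
  per2 <- clock_scenario("mouse_per2_LD", noise_cv = 0)
  t_p2 <- attr(per2$series, "truth")
  peak2 <- t_p2$time_h[which.min(abs(t_p2$X - max(t_p2$X)))] %% 24
  expect_gte(peak2, 9)   # maximal at/near the light-dark transition
  expect_lte(peak2, 12)
  # sampled truths repeat cycle-to-cycle: the scenarios are 1:1 entrained
  for (tt in list(t_frq, t_p1, t_p2)) {
    a <- approx(tt$time_h, tt$M_nM, xout = seq(0, 23.9, by = 0.5))$y
    b <- approx(tt$time_h, tt$M_nM, xout = seq(24, 47.9, by = 0.5))$y
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("identical scenario and seed give byte-identical CSV exports", {
  s1 <- clock_scenario("mouse_per1_LD", noise_cv = 0.1, seed = 3)$series
  s2 <- clock_scenario("mouse_per1_LD", noise_cv = 0.1, seed = 3)$series
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_expression(s1, f1)
  write_expression(s2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  ser <- read_expression(f1)
  expect_equal(ser$mrna_rel, s1$mrna_rel, tolerance = 1e-12)
})

test_that("invalid designs are rejected", {
  expect_error(sampling_design("LD", noise_cv = -0.1), "noise_cv")
  expect_error(sampling_design("LD", sample_times = c(0, 0, 2)), "increasing")
  des <- sampling_design("LD", sample_times = seq(0, 480, by = 24))
  expect_error(generate_observations(clock_params(),
                                     light_profile("square", x_max = 0.4),
                                     des), "exceed")
})
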