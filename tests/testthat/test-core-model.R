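test_that("the vector field at the origin reduces to unrepressed synthesis", {
  expect_equal(unname(clock_field(c(0, 0, 0), default_params)), c(1.6, 0, 0))
})

test_that("light scales only the synthesis term, linearly in (1 + X)", {
  p <- unclass(default_params)
  set.seed(21)
  for (i in 1:5) {
    s <- runif(3, 0, 5)
    d0 <- clock_field(s, default_params, x_light = 0)
    d1 <- clock_field(s, default_params, x_light = 1)
    hill <- p[["v_s"]] * p[["K_I"]]^p[["n"]] /
      (p[["K_I"]]^p[["n"]] + s[3]^p[["n"]])
    expect_equal(d1[["M"]] - d0[["M"]], hill, tolerance = 1e-12)
    expect_equal(d1[["P_C"]], d0[["P_C"]])
    expect_equal(d1[["P_N"]], d0[["P_N"]])
  }
  # Hill repression saturates: synthesis vanishes at large nuclear protein
  d <- clock_field(c(0, 0, 1e4), default_params)
  expect_gte(d[["M"]], 0)
  expect_lt(d[["M"]], 1e-10)
})

test_that("invalid states and parameters are rejected", {
  expect_error(clock_field(c(-1, 0, 0), default_params), "negative")
  expect_error(clock_field(c(0, 0, 0), default_params, x_light = -0.1), "x_light")
  expect_error(clock_params(v_s = -1), "strictly positive")
  expect_error(clock_params(n = 0.5), "n must be >= 1")
  expect_error(clock_params("unknown_set"), "unknown parameter set")
})

test_that("trajectories from the non-negative octant stay non-negative", {
  tr <- integrate_clock(default_params, t_span = c(0, 500), step = 0.01,
                        save_step = 0.05)
  expect_true(all(tr$M_nM >= 0 & tr$Pc_nM >= 0 & tr$Pn_nM >= 0))
  prof <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  tr2 <- integrate_clock(default_params, prof, t_span = c(0, 200))
  expect_true(all(tr2$M_nM >= 0 & tr2$Pc_nM >= 0 & tr2$Pn_nM >= 0))
})

test_that("step halving converges at fourth order on smooth segments", {
  tr1 <- integrate_clock(default_params, t_span = c(0, 200), step = 0.04,
                         save_step = 0.2)
  tr2 <- integrate_clock(default_params, t_span = c(0, 200), step = 0.02,
                         save_step = 0.2)
  tr3 <- integrate_clock(default_params, t_span = c(0, 200), step = 0.01,
                         save_step = 0.2)
  err12 <- max(abs(as.matrix(tr1[, 2:4]) - as.matrix(tr2[, 2:4])))
  err23 <- max(abs(as.matrix(tr2[, 2:4]) - as.matrix(tr3[, 2:4])))
  expect_lt(err23, 1e-6)      # halving from the default step
  expect_gt(err12 / err23, 8) # ~16x for a 4th-order scheme
})

test_that("the fixed-step integrator agrees with an adaptive reference", {
  skip_if_not_installed("deSolve")
  p <- unclass(default_params)
  f <- function(t, y, parms) {
    hill <- p[["K_I"]]^p[["n"]] / (p[["K_I"]]^p[["n"]] + y[3]^p[["n"]])
    list(c(p[["v_s"]] * hill - p[["v_m"]] * y[1] / (p[["K_M"]] + y[1]),
           p[["k_s"]] * y[1] - p[["v_d"]] * y[2] / (p[["K_d"]] + y[2]) -
             p[["k_1"]] * y[2] + p[["k_2"]] * y[3],
           p[["k_1"]] * y[2] - p[["k_2"]] * y[3]))
  }
  ref <- deSolve::ode(c(0.1, 0.1, 0.1), seq(0, 100, by = 1), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tr <- integrate_clock(default_params, t_span = c(0, 100), save_step = 1)
  expect_lt(max(abs(as.matrix(tr[, 2:4]) - ref[, 2:4])), 1e-5)
})

test_that("integrating one forcing period reproduces the stroboscopic map", {
  prof <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
  s <- c(1, 3, 2)
  tr <- integrate_clock(default_params, prof, init = s, t_span = c(0, 24),
                        save_step = 24)
  mapped <- stroboscopic_map(s, default_params, prof)
  expect_equal(as.numeric(tr[nrow(tr), 2:4]), mapped, tolerance = 1e-12)
})

test_that("the free-running period is invariant to the starting point", {
  lc <- lc_default()
  expect_equal(lc$period, 21.51, tolerance = 0.005)
  set.seed(5)
  lc2 <- find_limit_cycle(default_params, init = runif(3, 0.05, 2))
  lc3 <- find_limit_cycle(default_params, init = runif(3, 0.05, 2))
  expect_lt(abs(lc2$period - lc3$period), 1e-3)
  expect_lt(abs(lc2$period - lc$period), 1e-3)
  # cycle endpoints close up (to ~0.1% of the oscillation amplitude)
  cyc <- lc$cycle
  expect_lt(max(abs(as.numeric(cyc[nrow(cyc), 2:4]) - as.numeric(cyc[1, 2:4]))),
            0.01)
})

test_that("the period grows monotonically with the transcription rate", {
  tab <- period_scan(default_params, c(1.3, 1.6, 2.5, 3.2))
  expect_true(all(diff(tab$period_h) > 0))
  fine <- period_scan(default_params, seq(1.4, 3.0, by = 0.2))
  expect_true(all(diff(fine$period_h) > 0))
})

test_that("non-oscillatory parameters are reported, not silently returned", {
  expect_error(find_limit_cycle(clock_params(n = 1.2), transient = 300,
                                span = 300),
               "no sustained oscillation|fewer than 10")
})

test_that("trajectories round-trip through the CSV schema", {
  tr <- integrate_clock(default_params, t_span = c(0, 10), save_step = 0.5)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  expect_identical(readLines(path, n = 1), "time_h,M_nM,Pc_nM,Pn_nM,light_on")
  tr2 <- read_trajectory(path)
  expect_equal(tr2$M_nM, tr$M_nM, tolerance = 1e-6)
})
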