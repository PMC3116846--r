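dense_design <- function(dt = 0.25, span = 48, noise = 0, seed = 1)
  sampling_design("LD", sample_times = seq(0, span, by = dt),
                  noise_cv = noise, seed = seed)

test_that("cytosolic protein is recovered from dense noiseless data", {
  p <- clock_params("mammal_25h")
  prof <- light_profile("adaptation", x_max = 3, t_s = 4, t_d = 8)
  ser <- generate_observations(p, prof, dense_design())
  truth <- attr(ser, "truth")
  cyto <- estimate_cytosolic(ser, p, scales = attr(ser, "scales_true"))
  pc_t <- approx(truth$time_h, truth$Pc_nM, xout = cyto$time_h)$y
  rel <- sqrt(mean((cyto$pc_nM - pc_t)^2)) / sqrt(mean(pc_t^2))
  expect_lt(rel, 0.05)
  # conservation holds exactly by construction
  expect_equal(cyto$pc_nM + cyto$pn_nM, cyto$pt_nM, tolerance = 1e-12)
})

test_that("the pointwise inversion solves the algebraic balance in degenerate cases", {
  p <- unclass(clock_params())
  # constant M and P_t: P_C solves v_d Pc/(K_d + Pc) = k_s M
  ser <- expression_series(seq(0, 36, by = 2), rep(1, 19), rep(2, 19),
                           schedule = "DD", period = 24)
  cyto <- estimate_cytosolic(ser, clock_params(), scales = c(mrna = 1, protein = 1))
  r <- p[["k_s"]] * 1
  pc_expected <- p[["K_d"]] * r / (p[["v_d"]] - r)
  expect_equal(mean(cyto$pc_nM), pc_expected, tolerance = 1e-3)
  expect_lt(diff(range(cyto$pc_nM)), 1e-3)
  # dP_t/dt = k_s M exactly (no degradation signal) drives P_C to zero
  tt <- seq(0, 36, by = 2)
  ser2 <- expression_series(tt, rep(1, 19), 1 + p[["k_s"]] * tt,
                            schedule = "DD", period = 24)
  cyto2 <- estimate_cytosolic(ser2, clock_params(), scales = c(mrna = 1, protein = 1))
  expect_lt(max(cyto2$pc_nM), 1e-6)
})

test_that("a constant transcription rate is recovered flat", {
  p <- clock_params()
  des <- sampling_design("DD", cycle_period = 21.5,
                         sample_times = seq(0, 44, by = 0.1), noise_cv = 0)
  ser <- generate_observations(p, NULL, des)
  est <- suppressWarnings(
    estimate_response(ser, p, scales = attr(ser, "scales_true"),
                      classify = FALSE))
  vs <- est$grid$vs_nM_per_h
  expect_lt(max(abs(vs - 1.6)) / 1.6, 0.02)
})

test_that("dense noiseless closed loop recovers X(t) and the dark baseline", {
  p <- clock_params()
  prof <- light_profile("adaptation", x_max = 9, t_s = 1, t_d = 11)
  ser <- generate_observations(p, prof, dense_design())
  truth <- attr(ser, "truth")
  est <- suppressWarnings(
    estimate_response(ser, p, scales = attr(ser, "scales_true")))
  xt <- approx(truth$time_h, truth$X, xout = est$grid$time_h)$y
  nrmse <- sqrt(mean((est$grid$X - xt)^2)) / diff(range(xt))
  expect_lt(nrmse, 0.10)
  expect_equal(est$vs_dark, 1.6, tolerance = 0.02)
  expect_identical(est$shape$label, "adaptation")
  # recovered response peaks within 1 h of lights-on
  peak <- est$grid$time_h[which.max(est$grid$X)] %% 24
  expect_lte(peak, 1)
  # dark-phase response is flat around zero for an adaptation truth
  dark <- est$grid$light_on == 0
  expect_lt(mean(abs(est$grid$X[dark])), 0.1)
})

test_that("the slow-response truth is recovered with its late peak", {
  # the per2-like signal is weak (X_max = 0.25), so use the trajectory route
  p <- clock_params("mammal_25h")
  prof <- light_profile("slow_response", x_max = 0.25, t_r = 9, t_s = 3)
  ser <- generate_observations(p, prof, dense_design(dt = 2))
  est <- suppressWarnings(
    estimate_response(ser, p, scales = attr(ser, "scales_true"),
                      method = "trajectory"))
  expect_identical(est$shape$label, "slow_response")
  lit <- est$grid$light_on == 1
  peak <- (est$grid$time_h[lit])[which.max(est$grid$X[lit])] %% 24
  expect_gte(peak, 8)
  expect_lte(peak, 12)
})

test_that("estimation is scale-equivariant", {
  p <- clock_params("mammal_25h")
  prof <- light_profile("adaptation", x_max = 3, t_s = 4, t_d = 8)
  ser <- generate_observations(p, prof, dense_design(dt = 1))
  scl <- attr(ser, "scales_true")
  est1 <- suppressWarnings(estimate_response(ser, p, scales = scl))
  ser2 <- ser
  ser2$mrna_rel <- ser$mrna_rel * 7
  ser2$protein_total_rel <- ser$protein_total_rel * 0.3
  scl2 <- c(mrna = scl[["mrna"]] / 7, protein = scl[["protein"]] / 0.3)
  est2 <- suppressWarnings(estimate_response(ser2, p, scales = scl2))
  # equivariance holds to the estimator's own precision: rescaling perturbs
  # the spline inputs at machine precision, and the inversion amplifies that
  # by the Hill factor, so compare on the conditioning-weighted scale and on
  # the well-conditioned region
  d <- abs(est2$grid$X - est1$grid$X)
  expect_lt(max(d * sqrt(est1$grid$weight)), 0.01)
  expect_lt(max(d[est1$grid$weight > 4e-4]), 0.05)
  expect_equal(est2$vs_dark, est1$vs_dark, tolerance = 0.01)
})

test_that("heavy clipping is flagged as model misfit", {
  # protein series inconsistent with the mRNA series forces negative rates
  tt <- seq(0, 36, by = 1)
  ser <- expression_series(tt, 1 + 0.9 * sin(tt / 3), rep(1, length(tt)),
                           schedule = "DD", period = 24)
  expect_warning(
    estimate_response(ser, clock_params(), scales = c(mrna = 5, protein = 5),
                      classify = FALSE),
    "misfit")
})

test_that("dark parameters are recovered from noiseless free-running data", {
  sc <- clock_scenario("dd_fit", noise_cv = 0)
  init <- clock_params(v_s = 1.9, v_m = 0.45, v_d = 1.6)
  fit <- fit_dark_parameters(sc$series, params_init = init)
  truth <- unclass(clock_params())
  for (nm in c("v_s", "v_m", "v_d"))
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 0.05)
  expect_lt(abs(fit$period - 21.51), 0.2)
})

test_that("freezing all parameters returns scale factors and the direct mismatch", {
  sc <- clock_scenario("dd_fit", noise_cv = 0)
  fit <- fit_dark_parameters(sc$series, free = character(0))
  expect_named(fit$scales, c("mrna", "protein"))
  # the residual is the aligned trajectory mismatch; noiseless data fit well
  expect_lt(fit$residual, 0.05)
  expect_error(fit_dark_parameters(sc$series, free = "nonsense"),
               "unknown free parameter")
})

test_that("the free-running period survives measurement noise in the fit", {
  periods <- vapply(1:6, function(sd) {
    des <- sampling_design("DD", cycle_period = 21.5,
                           sample_times = seq(0, 43, length.out = 27),
                           noise_cv = 0.1, seed = sd)
    ser <- generate_observations(clock_params(), NULL, des)
    fit <- fit_dark_parameters(ser, params_init = clock_params(v_s = 1.8),
                               free = "v_s", n_starts = 1, maxit = 120)
    fit$period
  }, numeric(1))
  expect_lt(median(abs(periods - 21.51)), 0.5)
})

test_that("template classification identifies each truth shape", {
  tt <- seq(0, 30, by = 0.1)
  lon <- as.integer(tt %% 24 < 12)
  u <- tt %% 24
  x_ad <- ifelse(u < 3, 2, ifelse(u < 3 + 6, 2 * (1 - (u - 3) / 6), 0)) *
    (u < 12)
  cl <- classify_response(tt, x_ad, lon)
  expect_identical(cl$label, "adaptation")
  expect_lt(abs(cl$params[["T_d"]] - 6) / 6, 0.2)
  x_sq <- 1.5 * (u < 12)
  expect_identical(classify_response(tt, x_sq, lon)$label, "no_adaptation")
  x_sl <- ifelse(u < 9, 0.8 * u / 9, 0.8) * (u < 12)
  expect_identical(classify_response(tt, x_sl, lon)$label, "slow_response")
  # a shape matching no template is reported as other
  x_odd <- sin(2 * pi * u / 6)^2 * (u < 12)
  expect_identical(classify_response(tt, x_odd, lon)$label, "other")
})

test_that("estimated responses export with the documented schema", {
  p <- clock_params()
  prof <- light_profile("adaptation", x_max = 9, t_s = 1, t_d = 11)
  ser <- generate_observations(p, prof, dense_design(dt = 1))
  est <- suppressWarnings(
    estimate_response(ser, p, scales = attr(ser, "scales_true"),
                      classify = FALSE))
  path <- tempfile(fileext = ".csv")
  write_estimated_response(est, path)
  expect_identical(readLines(path, n = 1), "time_h,vs_nM_per_h,X")
})
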