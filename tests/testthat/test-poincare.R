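fig3c_profile <- light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)

test_that("the monodromy matrix matches a finite-difference map Jacobian", {
  s <- c(1, 3, 2)
  mo <- monodromy(s, default_params, fig3c_profile)
  h <- 1e-6
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J[, j] <- (stroboscopic_map(s + e, default_params, fig3c_profile) -
               stroboscopic_map(s - e, default_params, fig3c_profile)) / (2 * h)
  }
  expect_lt(max(abs(mo$monodromy - J)), 1e-5)
  # flow of a smooth field between breakpoints: positive determinant equal to
  # the multiplier product
  expect_gt(det(mo$monodromy), 0)
  mu <- eigen(mo$monodromy, only.values = TRUE)$values
  expect_equal(prod(Mod(mu)), det(mo$monodromy), tolerance = 1e-2)
})

test_that("the unforced monodromy over one period has a unit Floquet multiplier", {
  lc <- lc_default()
  mo <- monodromy(lc$state0, default_params, NULL, t_len = lc$period)
  mu <- eigen(mo$monodromy, only.values = TRUE)$values
  expect_lt(min(abs(Mod(mu) - 1)), 1e-4)
})

test_that("map composition has the semigroup property", {
  s <- c(0.5, 2, 1.5)
  three <- stroboscopic_map(s, default_params, fig3c_profile, n = 3)
  s1 <- stroboscopic_map(s, default_params, fig3c_profile)
  s2 <- stroboscopic_map(s1, default_params, fig3c_profile)
  s3 <- stroboscopic_map(s2, default_params, fig3c_profile)
  expect_equal(as.numeric(three[3, ]), s3, tolerance = 1e-12)
})

test_that("zero forcing gives the constant-darkness time-T flow and no locking", {
  none <- light_profile("none")
  s <- c(1, 1, 1)
  m1 <- stroboscopic_map(s, default_params, none)
  tr <- integrate_clock(default_params, init = s, t_span = c(0, 24),
                        save_step = 24)
  expect_equal(m1, as.numeric(tr[nrow(tr), 2:4]), tolerance = 1e-12)
  # the free-running 21.5-h clock cannot 1:1-lock to a 24-h section
  expect_error(find_entrained_orbit(default_params, none),
               "not entrained|no convergence")
})

test_that("the entrained orbit under moderate adaptation forcing is a stable fixed point", {
  fp <- find_entrained_orbit(default_params, fig3c_profile)
  expect_true(fp$stable)
  expect_lt(fp$residual, 1e-8)
  mapped <- stroboscopic_map(fp$state, default_params, fig3c_profile)
  expect_lt(max(abs(mapped - fp$state)), 1e-8)
  expect_true(all(Mod(fp$multipliers) < 1))
})

test_that("stable orbits attract perturbed starts and unstable ones repel", {
  fp <- find_entrained_orbit(default_params, fig3c_profile)
  pert <- fp$state + 1e-3
  it <- stroboscopic_map(pert, default_params, fig3c_profile, n = 300)
  expect_lt(max(abs(it[300, ] - fp$state)), 1e-6)
  # past the period doubling the fixed point persists but repels
  sq75 <- light_profile("square", x_max = 0.75)
  fp2 <- find_entrained_orbit(default_params, sq75,
                              guess = square_limits()$pd$fixed_point$state)
  expect_false(fp2$stable)
  it2 <- stroboscopic_map(fp2$state + 1e-3, default_params, sq75, n = 60)
  dists <- sqrt(rowSums((it2 - matrix(fp2$state, 60, 3, byrow = TRUE))^2))
  expect_gt(max(dists), 1e-2)
})

test_that("bisection demands a sign change across the bracket", {
  fam <- function(x) light_profile("square", x_max = x)
  expect_error(
    locate_bifurcation(default_params, fam, c(0.3, 0.45), "PD"),
    "no sign change")
})

test_that("entrainment limits bound a period-1 region for the square wave", {
  lim <- square_limits()
  expect_lt(lim$x_lower, lim$x_upper)
  # multiplier signatures at the located points
  expect_lt(abs(max(Re(lim$sn$multipliers)) - 1), 0.05)
  expect_lt(abs(min(Re(lim$pd$multipliers)) + 1), 0.05)
  inside <- classify_attractor(default_params,
                               light_profile("square", x_max = 0.4),
                               transient_cycles = 300, sample_cycles = 100)
  expect_identical(inside$label, "entrained-1T")
})

test_that("weak forcing leaves the oscillation quasi-periodic", {
  cl <- classify_attractor(default_params,
                           light_profile("adaptation", x_max = 0.125,
                                         t_s = 6, t_d = 6),
                           transient_cycles = 300, sample_cycles = 300)
  expect_identical(cl$label, "quasiperiodic")
  expect_lt(abs(cl$lyapunov), 0.01)
})

test_that("the one-parameter diagram separates locked and unlocked amplitudes", {
  d <- one_parameter_diagram(default_params, c(0.125, 0.75),
                             transient_cycles = 300, keep = 32)
  spread <- tapply(d$M_section, d$X_max, function(v) diff(range(v)))
  expect_gt(spread[["0.125"]], 1e-2)  # quasi-periodic band
  expect_lt(spread[["0.75"]], 1e-6)   # single entrained value
})

test_that("the two-parameter scan is consistent with the fixed-period limits and tongue shape", {
  sc <- two_parameter_scan(default_params, c(22, 24), kind = "adaptation",
                           x_seed = 0.4)
  sn <- sc[sc$type == "SN", ]
  expect_setequal(sn$T_h, c(22, 24))
  # slice at T = 24 must agree with the dedicated limit finder
  lim24 <- entrainment_limits(default_params, t_s = 3, kind = "adaptation")
  expect_equal(sn$X_crit[sn$T_h == 24], lim24$x_lower, tolerance = 1e-3)
  # Arnold tongue: the locking threshold grows with |T - tau|
  expect_lt(sn$X_crit[sn$T_h == 22], sn$X_crit[sn$T_h == 24])
  # upper boundary typed by its multiplier signature
  up <- sc[sc$type %in% c("PD", "NS"), ]
  expect_true(all(up$X_crit > sn$X_crit[match(up$T_h, sn$T_h)]))
})
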