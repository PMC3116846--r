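#' Expression time-series container
#'
#' Validates and packages sparse observations of relative mRNA abundance and
#' relative total protein abundance (unit-free, as expression data are
#' reported) together with their lighting annotation.
#'
#' @param time_h sample times (h), strictly increasing, >= 6 samples spanning
#'   at least one cycle.
#' @param mrna_rel relative mRNA abundance (>= 0).
#' @param protein_total_rel relative total protein abundance (>= 0).
#' @param light_on 0/1 lighting annotation per sample.
#' @param schedule `"LD"` or `"DD"`.
#' @param period cycle length used for the "spans one cycle" check (h).
#' @param photoperiod light-phase length (h), LD only.
#' @return a data frame of class `expression_series` with the four columns
#'   and schedule metadata in attributes.
#' @export
expression_series <- function(time_h, mrna_rel, protein_total_rel,
                              light_on = 0L, schedule = c("LD", "DD"),
                              period = 24, photoperiod = period / 2) {
  schedule <- match.arg(schedule)
  n <- length(time_h)
  if (n < 6) stop("need at least 6 samples")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (time_h[n] - time_h[1] < period - 1e-9)
    stop("samples must span at least one cycle (", period, " h)")
  if (any(mrna_rel < 0) || any(protein_total_rel < 0))
    stop("abundances must be >= 0")
  df <- data.frame(time_h = time_h, mrna_rel = mrna_rel,
                   protein_total_rel = protein_total_rel,
                   light_on = as.integer(rep_len(light_on, n)))
  class(df) <- c("expression_series", "data.frame")
  attr(df, "schedule") <- schedule
  attr(df, "period") <- period
  attr(df, "photoperiod") <- photoperiod
  df
}

#' Expression CSV import/export
#'
#' Schema `time_h,mrna_rel,protein_total_rel,light_on`.
#' @param series an `expression_series`.
#' @param path file path.
#' @param schedule,period,photoperiod metadata for [expression_series()]
#'   (not stored in the CSV).
#' @export
write_expression <- function(series, path) {
  utils::write.csv(as.data.frame(series)[, c("time_h", "mrna_rel",
                                             "protein_total_rel", "light_on")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, schedule = "LD", period = 24,
                            photoperiod = period / 2) {
  df <- utils::read.csv(path)
  expression_series(df$time_h, df$mrna_rel, df$protein_total_rel, df$light_on,
                    schedule = schedule, period = period,
                    photoperiod = photoperiod)
}

# smoothing spline, optionally with periodic folding: for series sampled on a
# T-periodic attractor the data are folded mod T and replicated one period to
# each side, giving periodic boundary behavior and cross-cycle averaging
fit_spline <- function(times, y, periodic_T = NULL) {
  # fit on unit-scale data so the GCV smoothing choice is scale-invariant
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  ys <- y / s
  sp <- if (is.null(periodic_T)) {
    stats::smooth.spline(times, ys)
  } else {
    u <- times %% periodic_T
    stats::smooth.spline(c(u - periodic_T, u, u + periodic_T), rep(ys, 3))
  }
  structure(list(sp = sp, T = periodic_T, scale = s), class = "scaled_spline")
}

predict_spline <- function(fit, x, deriv = 0) {
  xx <- if (is.null(fit$T)) x else x %% fit$T
  fit$scale * stats::predict(fit$sp, xx, deriv = deriv)$y
}

series_periodic_T <- function(series, periodic) {
  if (isTRUE(periodic)) attr(series, "period") else NULL
}

# periodic model prediction helpers -----------------------------------------

cycle_lookup <- function(lc, what = c("M_nM", "Pt")) {
  cyc <- lc$cycle
  y <- if (identical(what, "Pt")) cyc$Pc_nM + cyc$Pn_nM else cyc[[what]]
  function(t) {
    tt <- t %% lc$period
    stats::approx(cyc$time_h, y, xout = tt, rule = 2)$y
  }
}

# SS of (obs - s * pred) minimized over the scalar s; returns list(ss, s)
scaled_ss <- function(obs, pred) {
  s <- sum(obs * pred) / sum(pred^2)
  list(ss = sum((obs - s * pred)^2), s = s)
}

align_and_scale <- function(series, lc, phase_grid_step = 0.25) {
  fM <- cycle_lookup(lc, "M_nM")
  fP <- cycle_lookup(lc, "Pt")
  at_phase <- function(phi) {
    rM <- scaled_ss(series$mrna_rel, fM(series$time_h + phi))
    rP <- scaled_ss(series$protein_total_rel, fP(series$time_h + phi))
    list(ss = rM$ss + rP$ss, phase = phi, s_mrna = rM$s, s_protein = rP$s)
  }
  phis <- seq(0, lc$period - 1e-9, by = phase_grid_step)
  best <- NULL
  for (phi in phis) {
    cand <- at_phase(phi)
    if (is.null(best) || cand$ss < best$ss) best <- cand
  }
  # continuous refinement around the best grid phase
  op <- stats::optimize(function(phi) at_phase(phi)$ss,
                        best$phase + c(-1, 1) * phase_grid_step, tol = 1e-5)
  if (op$objective < best$ss) best <- at_phase(op$minimum)
  best
}

#' Fit dark-condition model parameters to expression data
#'
#' Least-squares fit of the free-running limit cycle (shape, period, and the
#' relative phase of M versus total protein) to a constant-darkness series.
#' Observations are relative; two multiplicative scale factors mapping
#' relative units to nM are profiled out in closed form, and the phase offset
#' between data and model is optimized on a grid. Kinetic parameters listed
#' in `free` are fitted by Nelder--Mead on the log scale from `n_starts`
#' perturbed starting points.
#'
#' @param dd_series an [expression_series()] under DD.
#' @param params_init starting [clock_params()].
#' @param free names of kinetic parameters to fit (default
#'   `c("v_s", "v_m", "v_d")`); an empty vector freezes everything and
#'   returns the scale factors and direct trajectory mismatch only.
#' @param n_starts multi-start budget.
#' @param transient,span passed to [find_limit_cycle()] during fitting.
#' @param maxit Nelder--Mead iteration cap per start.
#' @return an object of class `dark_fit`: list with `params` (fitted
#'   [clock_params()]), `scales` (named: nM per relative unit for `mrna`,
#'   `protein`... stored as relative-to-nM multipliers), `phase`, `residual`
#'   (sum of squares), `period`, `convergence`.
#' @export
fit_dark_parameters <- function(dd_series, params_init = clock_params(),
                                free = c("v_s", "v_m", "v_d"), n_starts = 3,
                                transient = 300, span = 320, maxit = 300) {
  stopifnot(inherits(dd_series, "expression_series"))
  if (!identical(attr(dd_series, "schedule"), "DD"))
    warning("series is not annotated as DD; fitting the free-running cycle anyway")
  p0 <- as_params_vec(params_init)
  eval_params <- function(p) {
    lc <- tryCatch(find_limit_cycle(structure(p, class = "clock_params"),
                                    transient = transient, span = span),
                   error = function(e) NULL)
    if (is.null(lc)) return(NULL)
    al <- align_and_scale(dd_series, lc)
    list(lc = lc, al = al)
  }
  if (!length(free)) {
    ev <- eval_params(p0)
    if (is.null(ev)) stop("initial parameters are non-oscillatory")
    return(structure(list(params = structure(p0, class = "clock_params"),
                          scales = c(mrna = 1 / ev$al$s_mrna,
                                     protein = 1 / ev$al$s_protein),
                          phase = ev$al$phase, residual = ev$al$ss,
                          period = ev$lc$period, convergence = 0L),
                     class = "dark_fit"))
  }
  bad <- setdiff(free, names(p0))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  obj <- function(logth) {
    p <- p0
    p[free] <- exp(logth)
    ev <- eval_params(p)
    if (is.null(ev)) return(1e6)  # non-oscillatory: rejected
    ev$al$ss
  }
  starts <- list(log(p0[free]))
  if (n_starts > 1) {
    fac <- c(0.8, 1.25, 0.65, 1.5)
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- log(p0[free] * fac[((k - 1) %% length(fac)) + 1])
  }
  best <- NULL
  if (length(free) == 1) {
    op <- stats::optimize(function(l) obj(l),
                          log(p0[free]) + c(-1, 1) * log(3), tol = 1e-7)
    best <- list(par = op$minimum, value = op$objective, convergence = 0L)
  } else {
    for (st in starts) {
      op <- stats::optim(st, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9))
      if (is.null(best) || op$value < best$value) best <- op
    }
  }
  if (best$value >= 1e6)
    stop("non-convergence: every start ended in the non-oscillatory regime")
  p <- p0
  p[free] <- exp(best$par)
  ev <- eval_params(p)
  structure(list(params = structure(p, class = "clock_params"),
                 scales = c(mrna = 1 / ev$al$s_mrna,
                            protein = 1 / ev$al$s_protein),
                 phase = ev$al$phase, residual = ev$al$ss,
                 period = ev$lc$period, convergence = best$convergence),
            class = "dark_fit")
}

#' @export
print.dark_fit <- function(x, ...) {
  cat(sprintf("<dark_fit> period %.3f h, residual %.4g, phase %.2f h\n",
              x$period, x$residual, x$phase))
  cat(sprintf("  scales (nM per relative unit): mrna %.4g, protein %.4g\n",
              x$scales["mrna"], x$scales["protein"]))
  invisible(x)
}

#' Reconstruct cytosolic protein from total protein and mRNA
#'
#' Adding the two protein equations of the model eliminates nuclear
#' transport, leaving dP_t/dt = k_s M - v_d P_C / (K_d + P_C). Given a
#' smoothing-spline fit of P_t(t) (smoothing parameter by generalized
#' cross-validation) this is inverted pointwise for P_C on a dense grid:
#' P_C = K_d r / (v_d - r) with r = k_s M - dP_t/dt, clamped to [0, P_t].
#' Grid points with no finite solution (r >= v_d) or P_C above P_t are
#' clamped to P_t and flagged.
#'
#' @param series an [expression_series()].
#' @param params a [clock_params()] object (dark parameters).
#' @param scales named multipliers converting relative units to nM
#'   (`mrna`, `protein`), e.g. from [fit_dark_parameters()].
#' @param grid_step dense-grid spacing (h).
#' @param periodic treat the series as sampled on a T-periodic attractor and
#'   fit folded (periodic) smoothing splines (off by default).
#' @return data frame with columns `time_h, m_nM, pt_nM, pc_nM, pn_nM,
#'   clamped`; `pc_nM + pn_nM` equals the spline-fitted total protein by
#'   construction.
#' @export
estimate_cytosolic <- function(series, params, scales = c(mrna = 1, protein = 1),
                               grid_step = 0.1, periodic = FALSE) {
  stopifnot(inherits(series, "expression_series"))
  p <- as_params_vec(params)
  pT <- series_periodic_T(series, periodic)
  spM <- fit_spline(series$time_h, series$mrna_rel * scales[["mrna"]], pT)
  spP <- fit_spline(series$time_h,
                    series$protein_total_rel * scales[["protein"]], pT)
  grid <- seq(min(series$time_h), max(series$time_h), by = grid_step)
  M <- pmax(predict_spline(spM, grid), 0)
  Pt <- pmax(predict_spline(spP, grid), 0)
  dPt <- predict_spline(spP, grid, deriv = 1)
  r <- p[["k_s"]] * M - dPt
  pc <- numeric(length(grid))
  clamped <- logical(length(grid))
  pos <- r > 0
  finite_sol <- pos & r < p[["v_d"]]
  pc[finite_sol] <- p[["K_d"]] * r[finite_sol] / (p[["v_d"]] - r[finite_sol])
  pc[pos & !finite_sol] <- Pt[pos & !finite_sol]
  clamped[pos & !finite_sol] <- TRUE
  over <- pc > Pt
  clamped[over] <- TRUE
  pc[over] <- Pt[over]
  data.frame(time_h = grid, m_nM = M, pt_nM = Pt, pc_nM = pc,
             pn_nM = Pt - pc, clamped = clamped)
}

#' Invert the mRNA equation for the transcription rate
#'
#' Substitutes the (spline-smoothed) mRNA series and the reconstructed
#' nuclear protein into the transcription equation and solves for the
#' time-varying rate:
#' v_s(t) = (dM/dt + v_m M / (K_M + M)) (K_I^n + P_N^n) / K_I^n.
#' Negative excursions are clipped to zero and flagged; clipping on more
#' than 20\% of grid points flags model misfit with a warning.
#'
#' @param series an [expression_series()].
#' @param cytosolic the dense grid from [estimate_cytosolic()].
#' @param params a [clock_params()] object.
#' @param scales as in [estimate_cytosolic()] (the same values must be used).
#' @param periodic as in [estimate_cytosolic()].
#' @return data frame with columns `time_h, vs_nM_per_h, clipped`.
#' @export
invert_vs <- function(series, cytosolic, params,
                      scales = c(mrna = 1, protein = 1), periodic = FALSE) {
  p <- as_params_vec(params)
  pT <- series_periodic_T(series, periodic)
  spM <- fit_spline(series$time_h, series$mrna_rel * scales[["mrna"]], pT)
  grid <- cytosolic$time_h
  M <- pmax(predict_spline(spM, grid), 0)
  dM <- predict_spline(spM, grid, deriv = 1)
  KIn <- p[["K_I"]]^p[["n"]]
  vs <- (dM + p[["v_m"]] * M / (p[["K_M"]] + M)) *
    (KIn + cytosolic$pn_nM^p[["n"]]) / KIn
  clipped <- vs < 0
  vs[clipped] <- 0
  if (mean(clipped) > 0.2)
    warning(sprintf("model misfit: %.0f%% of grid points required clipping v_s at 0",
                    100 * mean(clipped)))
  data.frame(time_h = grid, vs_nM_per_h = vs, clipped = clipped)
}

light_on_grid <- function(series, grid) {
  if (identical(attr(series, "schedule"), "DD"))
    return(rep(0L, length(grid)))
  Tt <- attr(series, "period")
  L <- attr(series, "photoperiod")
  as.integer((grid %% Tt) < L)
}

#' Full transcription-rate reconstruction
#'
#' Chains [estimate_cytosolic()] and [invert_vs()], derives the dimensionless
#' light response X(t) = v_s(t)/v_s_dark - 1 (dark baseline: conditioning-
#' weighted mean rate over the last 6 h of the dark phase), and classifies
#' the light-phase response shape with [classify_response()].
#'
#' The inversion multiplies spline-derivative error by the Hill factor
#' (K_I^n + P_N^n)/K_I^n, which spans orders of magnitude across the cycle:
#' v_s is well determined only where nuclear protein is low. The returned
#' grid carries a conditioning weight per point (inverse squared
#' amplification, zero where the P_C inversion clamped) as a reliability
#' diagnostic.
#'
#' `method = "trajectory"` switches from pointwise spline inversion to a
#' trajectory-level fit: X(t) is parameterized as a piecewise-linear profile
#' on knots across the light phase (zero in the dark), the entrained orbit is
#' simulated for each candidate profile, and the knot values are fitted by
#' least squares against the observed series. This avoids derivative
#' amplification entirely and is the appropriate route for sparse or noisy
#' sampling; it assumes the data lie on the 1:1 entrained attractor.
#'
#' @inheritParams estimate_cytosolic
#' @param classify run template classification (LD series only).
#' @param method `"pointwise"` (default, spline inversion) or `"trajectory"`.
#' @param traj_control options for the trajectory fit: `maxit` (Nelder--Mead
#'   iterations per start, default 250), `starts` (X_max starting values,
#'   default c(0.3, 2, 8)), `reltol` (default 1e-8).
#' @return an object of class `estimated_response`: list with `grid` (data
#'   frame `time_h, vs_nM_per_h, X, weight, pc_nM, pn_nM, light_on`),
#'   `vs_dark`, `shape` (a [classify_response()] result or NULL),
#'   `clip_fraction`.
#' @export
estimate_response <- function(series, params, scales = c(mrna = 1, protein = 1),
                              grid_step = 0.1, classify = TRUE,
                              periodic = FALSE,
                              method = c("pointwise", "trajectory"),
                              traj_control = list()) {
  method <- match.arg(method)
  if (method == "trajectory")
    return(estimate_response_trajectory(series, params, scales, grid_step,
                                        classify, traj_control))
  cyto <- estimate_cytosolic(series, params, scales, grid_step, periodic)
  vs <- invert_vs(series, cyto, params, scales, periodic)
  grid <- cyto$time_h
  p <- as_params_vec(params)
  KIn <- p[["K_I"]]^p[["n"]]
  amp <- (KIn + cyto$pn_nM^p[["n"]]) / KIn  # error amplification factor
  w <- 1 / amp^2
  # points where the P_C inversion was clamped carry no usable information
  w[cyto$clamped] <- 0
  if (all(w == 0)) w[] <- 1
  lon <- light_on_grid(series, grid)
  dark_idx <- which(lon == 0)
  if (length(dark_idx)) {
    t_dark_end <- max(grid[dark_idx])
    sel <- dark_idx[grid[dark_idx] > t_dark_end - 6]
  } else {
    sel <- seq_along(grid)
  }
  vs_dark <- mean(vs$vs_nM_per_h[sel])
  x <- vs$vs_nM_per_h / vs_dark - 1
  out_grid <- data.frame(time_h = grid, vs_nM_per_h = vs$vs_nM_per_h, X = x,
                         weight = w, pc_nM = cyto$pc_nM, pn_nM = cyto$pn_nM,
                         light_on = lon)
  shape <- NULL
  if (classify && any(lon == 1))
    shape <- classify_response(grid, x, lon,
                               photoperiod = attr(series, "photoperiod"))
  structure(list(grid = out_grid, vs_dark = vs_dark, shape = shape,
                 clip_fraction = mean(vs$clipped), params = params,
                 scales = scales),
            class = "estimated_response")
}

#' @export
print.estimated_response <- function(x, ...) {
  cat(sprintf("<estimated_response> %d grid points, v_s(dark) = %.4g nM/h, X in [%.3g, %.3g]\n",
              nrow(x$grid), x$vs_dark, min(x$grid$X), max(x$grid$X)))
  if (!is.null(x$shape))
    cat(sprintf("  light-phase shape: %s (X_max %.3g)\n",
                x$shape$label, x$shape$params[["X_max"]]))
  invisible(x)
}

#' Estimated response CSV export
#'
#' Writes columns `time_h,vs_nM_per_h,X`.
#' @param response an [estimate_response()] result.
#' @param path file path.
#' @export
write_estimated_response <- function(response, path) {
  utils::write.csv(response$grid[, c("time_h", "vs_nM_per_h", "X")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify the shape of a recovered light response
#'
#' Fits the three light-induction templates to X(t) restricted to the first
#' complete light phase: adaptation (plateau T_s then linear decay T_d), slow
#' response (linear rise T_r then plateau ending at lights-off), and a
#' constant plateau (no adaptation). The label is chosen by an AIC-like
#' penalized residual, n log(RSS/n) + 2k; `"other"` is returned when even the
#' best template leaves a large relative residual. Only the light phase is
#' used: with real data the dark-phase response need not vanish (neglected
#' posttranslational regulation), and classification must not depend on it.
#'
#' @param time_h dense time grid (h).
#' @param x recovered response X on the grid.
#' @param light_on 0/1 lighting per grid point.
#' @param photoperiod light-phase length (h).
#' @param other_threshold relative RMSE above which the label is `"other"`.
#' @param weights optional per-point weights (e.g. the conditioning weights
#'   of [estimate_response()]); the template fit and its residual
#'   diagnostics are weighted.
#' @return list with `label` (`"adaptation"`, `"slow_response"`,
#'   `"no_adaptation"`, `"other"`), `params` (fitted `X_max`, `T_s`, `T_d`,
#'   `T_r`), and `fits` (per-template RSS and AIC).
#' @export
classify_response <- function(time_h, x, light_on, photoperiod = 12,
                              other_threshold = 0.35, weights = NULL) {
  on <- which(light_on == 1)
  if (!length(on)) stop("x_t must cover at least one light phase")
  # first complete light phase: from the first lights-on transition
  starts <- on[c(TRUE, diff(on) > 1)]
  t_on <- time_h[starts[1]]
  sel <- which(time_h >= t_on & time_h < t_on + photoperiod & light_on == 1)
  u <- time_h[sel] - t_on
  xu <- x[sel]
  wu <- if (is.null(weights)) rep(1, length(sel)) else weights[sel]
  wu <- wu / mean(wu)
  n <- length(u)
  L <- photoperiod
  tmpl_adapt <- function(th) {  # th = (X_max, a, b): Ts = a L, Td = b (L - Ts)
    Ts <- th[2] * L
    Td <- th[3] * (L - Ts)
    val <- ifelse(u < Ts, th[1],
                  ifelse(Td > 0 & u < Ts + Td, th[1] * (1 - (u - Ts) / Td), 0))
    val
  }
  tmpl_slow <- function(th) {  # th = (X_max, c): Tr = c L, plateau to L
    Tr <- th[2] * L
    ifelse(Tr > 0 & u < Tr, th[1] * u / Tr, th[1])
  }
  fit <- function(template, init, lower, upper) {
    rss <- function(th) sum(wu * (xu - template(th))^2)
    op <- stats::optim(init, rss, method = "L-BFGS-B",
                       lower = lower, upper = upper)
    # a couple of extra starts to dodge local minima in the breakpoints
    for (i2 in list(init * c(1, 0.5, 1)[seq_along(init)],
                    init * c(1, 1.5, 1)[seq_along(init)])) {
      i2 <- pmin(pmax(i2, lower), upper)
      op2 <- stats::optim(i2, rss, method = "L-BFGS-B",
                          lower = lower, upper = upper)
      if (op2$value < op$value) op <- op2
    }
    op
  }
  xm0 <- max(max(xu), 1e-3)
  f_ad <- fit(tmpl_adapt, c(xm0, 0.4, 0.8), c(0, 0, 0), c(10 * xm0, 1, 1))
  f_sl <- fit(tmpl_slow, c(xm0, 0.6), c(0, 0), c(10 * xm0, 1))
  rss_flat <- function(xm) sum(wu * (xu - xm)^2)
  xm_flat <- stats::weighted.mean(xu, wu)
  fits <- data.frame(
    template = c("adaptation", "slow_response", "no_adaptation"),
    rss = c(f_ad$value, f_sl$value, rss_flat(xm_flat)),
    k = c(3, 2, 1))
  fits$aic <- n * log(pmax(fits$rss, 1e-12) / n) + 2 * fits$k
  best <- which.min(fits$aic)
  label <- fits$template[best]
  pars <- switch(label,
    adaptation = {
      Ts <- f_ad$par[2] * L
      Td <- f_ad$par[3] * (L - Ts)
      c(X_max = f_ad$par[1], T_s = Ts, T_d = Td, T_r = 0)
    },
    slow_response = {
      Tr <- f_sl$par[2] * L
      c(X_max = f_sl$par[1], T_s = L - Tr, T_d = 0, T_r = Tr)
    },
    no_adaptation = c(X_max = xm_flat, T_s = L, T_d = 0, T_r = 0))
  # adaptation that degenerates to a full-length plateau is no adaptation
  if (label == "adaptation" && pars[["T_d"]] < 0.25 &&
      pars[["T_s"]] > 0.95 * L) {
    label <- "no_adaptation"
  }
  # robust guard: ill-conditioned grid points produce isolated spikes that a
  # median residual ignores, while a structurally wrong template leaves large
  # residuals across the whole phase
  resid_best <- switch(fits$template[best],
    adaptation = xu - tmpl_adapt(f_ad$par),
    slow_response = xu - tmpl_slow(f_sl$par),
    no_adaptation = xu - xm_flat)
  rel_rmse <- stats::median(abs(resid_best)) /
    max(stats::median(abs(xu - stats::median(xu))), abs(stats::median(xu)), 1e-9)
  if (rel_rmse > other_threshold) label <- "other"
  list(label = label, params = pars, fits = fits, rel_rmse = rel_rmse)
}


# trajectory-level reconstruction: fit each light-response template by
# simulating the entrained orbit it produces and matching the sampled
# observations; the label is the AIC-best template
estimate_response_trajectory <- function(series, params, scales, grid_step,
                                         classify, traj_control = list()) {
  maxit <- if (is.null(traj_control$maxit)) 250 else traj_control$maxit
  starts <- if (is.null(traj_control$starts)) c(0.3, 2, 8) else traj_control$starts
  reltol <- if (is.null(traj_control$reltol)) 1e-8 else traj_control$reltol
  Tt <- attr(series, "period")
  L <- attr(series, "photoperiod")
  if (identical(attr(series, "schedule"), "DD"))
    stop("trajectory-level estimation requires an LD series")
  par <- as_params_vec(params)
  m_obs <- series$mrna_rel * scales[["mrna"]]
  p_obs <- series$protein_total_rel * scales[["protein"]]
  u_s <- series$time_h %% Tt
  cache <- new.env()
  cache$y0 <- c(0.1, 0.1, 0.1)
  sim_knots <- function(kt, kx, dt = 0.1) {
    res <- cpp_integrate_knots(cache$y0, par, kt, kx, Tt, 10L, dt, dt)
    m <- res$cycle
    if (res$resid < 1e-8) cache$y0 <- as.numeric(m[nrow(m), 2:4])
    list(t = m[, 1], M = m[, 2], Pt = m[, 3] + m[, 4],
         Pc = m[, 3], Pn = m[, 4], resid = res$resid)
  }
  rss_of <- function(kt, kx) {
    sim <- sim_knots(kt, kx)
    mp <- stats::approx(sim$t, sim$M, xout = u_s, rule = 2)$y
    pp <- stats::approx(sim$t, sim$Pt, xout = u_s, rule = 2)$y
    rss <- sum((m_obs - mp)^2) + sum((p_obs - pp)^2)
    rss + 1e3 * max(sim$resid - 1e-8, 0)
  }
  eps <- 1e-6
  # templates parameterized on the unit cube (X_max log-scaled)
  knots_adapt <- function(th) {  # (log X_max, a, b): Ts = aL, Td = b(L - Ts)
    Ts <- th[2] * L; Td <- th[3] * (L - Ts)
    xm <- exp(th[1])
    kt <- c(0, max(Ts, eps), min(Ts + max(Td, eps), L))
    list(kt = kt, kx = c(xm, xm, 0))
  }
  knots_slow <- function(th) {  # (log X_max, c): Tr = cL, plateau to L
    Tr <- max(th[2] * L, eps)
    xm <- exp(th[1])
    list(kt = c(0, Tr, L), kx = c(0, xm, xm))
  }
  knots_flat <- function(th) {
    xm <- exp(th[1])
    list(kt = c(0, L), kx = c(xm, xm))
  }
  fit_template <- function(make, init, k) {
    f <- function(th) {
      th[-1] <- pmin(pmax(th[-1], 0), 1)
      kk <- make(th)
      rss_of(kk$kt, kk$kx)
    }
    best <- NULL
    for (x0 in init) {
      cache$y0 <- c(0.1, 0.1, 0.1)
      op <- stats::optim(x0, f, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
      if (is.null(best) || op$value < best$value) best <- op
    }
    best$par[-1] <- pmin(pmax(best$par[-1], 0), 1)
    best$k <- k
    best
  }
  lx0 <- log(starts)
  ad_init <- c(lapply(lx0, function(l) c(l, 0.4, 0.8)),
               lapply(lx0, function(l) c(l, 0.1, 0.9)))
  sl_init <- unlist(lapply(lx0, function(l)
    lapply(c(0.3, 0.6, 0.9), function(cc) c(l, cc))), recursive = FALSE)
  f_ad <- fit_template(knots_adapt, ad_init, 3)
  f_sl <- fit_template(knots_slow, sl_init, 2)
  f_fl <- {
    g <- function(l) rss_of(knots_flat(l)$kt, knots_flat(l)$kx)
    cache$y0 <- c(0.1, 0.1, 0.1)
    op <- stats::optimize(g, c(log(0.01), log(50)), tol = 1e-6)
    list(par = op$minimum, value = op$objective, k = 1)
  }
  n2 <- 2 * length(u_s)
  fits <- data.frame(template = c("adaptation", "slow_response", "no_adaptation"),
                     rss = c(f_ad$value, f_sl$value, f_fl$value),
                     k = c(3, 2, 1))
  fits$aic <- n2 * log(pmax(fits$rss, 1e-12) / n2) + 2 * fits$k
  best_i <- which.min(fits$aic)
  label <- fits$template[best_i]
  best_fit <- list(adaptation = f_ad, slow_response = f_sl,
                   no_adaptation = f_fl)[[label]]
  kk <- switch(label, adaptation = knots_adapt(best_fit$par),
               slow_response = knots_slow(best_fit$par),
               no_adaptation = knots_flat(best_fit$par))
  pars <- switch(label,
    adaptation = {
      Ts <- best_fit$par[2] * L; Td <- best_fit$par[3] * (L - Ts)
      c(X_max = exp(best_fit$par[1]), T_s = Ts, T_d = Td, T_r = 0)
    },
    slow_response = c(X_max = exp(best_fit$par[1]),
                      T_s = L - best_fit$par[2] * L, T_d = 0,
                      T_r = best_fit$par[2] * L),
    no_adaptation = c(X_max = exp(best_fit$par[1]), T_s = L, T_d = 0, T_r = 0))
  if (label == "adaptation" && pars[["T_d"]] < 0.25 && pars[["T_s"]] > 0.95 * L)
    label <- "no_adaptation"
  # guard: a template must explain most of the observed variance
  var_tot <- sum((m_obs - mean(m_obs))^2) + sum((p_obs - mean(p_obs))^2)
  if (fits$rss[best_i] > 0.5 * var_tot) label <- "other"
  cache$y0 <- c(0.1, 0.1, 0.1)
  sim <- sim_knots(kk$kt, kk$kx, dt = 0.02)
  grid <- seq(min(series$time_h), max(series$time_h), by = grid_step)
  ug <- grid %% Tt
  xfun <- function(u) {
    v <- stats::approx(kk$kt, kk$kx, xout = pmin(u, max(kk$kt)), rule = 2)$y
    ifelse(u >= max(kk$kt), 0, v)
  }
  x <- xfun(ug)
  lon <- light_on_grid(series, grid)
  out_grid <- data.frame(
    time_h = grid,
    vs_nM_per_h = par[["v_s"]] * (1 + x),
    X = x,
    weight = 1,
    pc_nM = stats::approx(sim$t, sim$Pc, xout = ug, rule = 2)$y,
    pn_nM = stats::approx(sim$t, sim$Pn, xout = ug, rule = 2)$y,
    light_on = lon)
  shape <- list(label = label, params = pars, fits = fits,
                rel_rmse = sqrt(fits$rss[best_i] / max(var_tot, 1e-12)))
  structure(list(grid = out_grid, vs_dark = par[["v_s"]], shape = shape,
                 clip_fraction = 0, params = params, scales = scales,
                 fit_rss = fits$rss[best_i]),
            class = "estimated_response")
}
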