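#' Sampling design for synthetic expression data
#'
#' Describes when a synthetic experiment samples the model and how noisy the
#' observations are. Noise is multiplicative lognormal (expression data are
#' relative and positive): observed = truth * exp(e), e ~ N(0, log(1+cv^2)),
#' so the coefficient of variation of observed/truth is `noise_cv`.
#'
#' @param schedule `"LD"` or `"DD"`.
#' @param cycle_period cycle length (h).
#' @param sample_times sampling grid (h, relative to the start of the
#'   post-warm-up window); default every 2 h over one cycle.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed (observations are deterministic given it).
#' @param photoperiod light-phase length (h).
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(schedule = c("LD", "DD"), cycle_period = 24,
                            sample_times = seq(0, cycle_period, by = 2),
                            noise_cv = 0.1, seed = 1,
                            photoperiod = cycle_period / 2) {
  schedule <- match.arg(schedule)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (any(diff(sample_times) <= 0)) stop("sample_times must be strictly increasing")
  structure(list(schedule = schedule, cycle_period = cycle_period,
                 sample_times = sample_times, noise_cv = noise_cv,
                 seed = as.integer(seed), photoperiod = photoperiod),
            class = "sampling_design")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate ground-truthed synthetic observations
#'
#' Simulates the clock model under a known light profile, discards warm-up
#' cycles (at least `warmup_cycles`, then continued until the once-per-cycle
#' state converges -- entrained scenarios can take tens to hundreds of cycles
#' to relax onto their attractor), samples mRNA and total protein at the
#' design's times, applies
#' multiplicative lognormal noise, and (by default) rescales each channel so
#' its maximum is 1 (relative units). The noiseless dense truth -- including
#' the true v_s(t) and X(t) -- is retained in attributes so estimation can be
#' validated closed-loop.
#'
#' @param params a [clock_params()] object (the truth).
#' @param profile a [light_profile()] or `NULL` for DD (the truth).
#' @param design a [sampling_design()].
#' @param relative rescale each observed channel to max 1.
#' @param warmup_cycles cycles discarded before sampling (>= 10).
#' @param step integration step (h).
#' @return an [expression_series()] with attributes `truth` (dense data frame
#'   `time_h, M_nM, Pc_nM, Pn_nM, Pt_nM, vs_nM_per_h, X`), `truth_params`,
#'   `truth_profile`, and `scales_true` (nM per relative unit actually
#'   applied).
#' @export
generate_observations <- function(params, profile, design, relative = TRUE,
                                  warmup_cycles = 50, step = 0.01) {
  stopifnot(inherits(design, "sampling_design"))
  if (warmup_cycles < 10) stop("warmup_cycles must be >= 10")
  period <- design$cycle_period
  warm <- warmup_cycles * period
  span <- max(design$sample_times)
  if (span > 10 * period) stop("sample times exceed the simulated span")
  par <- as_params_vec(params)
  pv <- profile_vec(profile)
  y <- cpp_final_state(c(0.1, 0.1, 0.1), par, pv, 0, warm, step)
  # continue cycle-by-cycle until the stroboscopic state has converged, so
  # entrained truths are sampled on the attractor, not on a slow transient
  t0 <- warm
  for (k in seq_len(1000)) {
    y_new <- cpp_final_state(y, par, pv, t0, t0 + period, step)
    t0 <- t0 + period
    if (max(abs(y_new - y)) < 1e-9) { y <- y_new; break }
    y <- y_new
  }
  warm <- t0
  tr <- cpp_integrate(y, par, pv, warm, warm + span + period, step, step)
  tt <- tr[, 1] - warm
  truth <- data.frame(time_h = tt, M_nM = tr[, 2], Pc_nM = tr[, 3],
                      Pn_nM = tr[, 4], Pt_nM = tr[, 3] + tr[, 4],
                      vs_nM_per_h = par[["v_s"]] * (1 + tr[, 5]),
                      X = tr[, 5])
  m_true <- stats::approx(tt, truth$M_nM, xout = design$sample_times)$y
  p_true <- stats::approx(tt, truth$Pt_nM, xout = design$sample_times)$y
  nobs <- length(design$sample_times)
  if (design$noise_cv > 0) {
    sdlog <- sqrt(log(1 + design$noise_cv^2))
    eps <- with_seed(design$seed, matrix(stats::rnorm(2 * nobs, 0, sdlog), ncol = 2))
    m_obs <- m_true * exp(eps[, 1])
    p_obs <- p_true * exp(eps[, 2])
  } else {
    m_obs <- m_true
    p_obs <- p_true
  }
  s_m <- if (relative) max(m_obs) else 1
  s_p <- if (relative) max(p_obs) else 1
  lon <- if (is.null(profile) || profile$kind == "none") rep(0L, nobs)
  else as.integer((design$sample_times %% period) < design$photoperiod)
  series <- expression_series(design$sample_times, m_obs / s_m, p_obs / s_p,
                              lon, schedule = design$schedule,
                              period = period,
                              photoperiod = design$photoperiod)
  attr(series, "truth") <- truth
  attr(series, "truth_params") <- params
  attr(series, "truth_profile") <- profile
  attr(series, "scales_true") <- c(mrna = s_m, protein = s_p)
  series
}

#' Preset synthetic scenarios
#'
#' Ground-truthed bundles emulating published sampling designs:
#'
#' Every preset's truth is a 1:1 entrained oscillation (as the emulated
#' experiments are); amplitudes are chosen inside the waveform family's
#' entrained band.
#'
#' * `"neurospora_frq_LD"`: 21.5-h oscillator, adaptation truth with a sharp
#'   rise at lights-on (peak within the first hour, X_max = 9 -- light
#'   induction of frq reaches roughly ten times the dark rate) followed by a
#'   gradual decay that reaches the dark level at lights-off (T_s = 1,
#'   T_d = 11).
#' * `"mouse_per1_LD"`: 25-h oscillator, adaptation truth whose plateau ends
#'   4 h after lights-on (X_max = 3, T_s = 4, T_d = 8).
#' * `"mouse_per2_LD"`: 25-h oscillator, slow-response truth ramping over 9 h
#'   and maximal at the light--dark transition (X_max = 0.25, T_r = 9,
#'   T_s = 3; the 25-h oscillator only entrains to this waveform on a narrow
#'   amplitude band).
#' * `"dd_fit"`: 21.5-h oscillator, unforced, 2-h sampling over two
#'   free-running cycles (the dark-parameter fitting scenario).
#'
#' LD presets sample every 2 h across two 24-h cycles.
#'
#' @param name preset name.
#' @param noise_cv,seed overrides for the sampling design.
#' @return a `scenario` object: list with `params`, `profile`, `design`, and
#'   a `series` generated from them (truth retained in its attributes).
#' @export
clock_scenario <- function(name = c("neurospora_frq_LD", "mouse_per1_LD",
                                    "mouse_per2_LD", "dd_fit"),
                           noise_cv = 0.1, seed = 1) {
  name <- match.arg(name)
  if (name == "dd_fit") {
    params <- clock_params("neurospora_21p5h")
    profile <- NULL
    design <- sampling_design("DD", cycle_period = 21.5,
                              sample_times = seq(0, 44, by = 2),
                              noise_cv = noise_cv, seed = seed)
  } else {
    design <- sampling_design("LD", cycle_period = 24,
                              sample_times = seq(0, 48, by = 2),
                              noise_cv = noise_cv, seed = seed)
    if (name == "neurospora_frq_LD") {
      params <- clock_params("neurospora_21p5h")
      profile <- light_profile("adaptation", x_max = 9, t_s = 1, t_d = 11)
    } else if (name == "mouse_per1_LD") {
      params <- clock_params("mammal_25h")
      profile <- light_profile("adaptation", x_max = 3, t_s = 4, t_d = 8)
    } else {
      params <- clock_params("mammal_25h")
      profile <- light_profile("slow_response", x_max = 0.25, t_r = 9, t_s = 3)
    }
  }
  series <- generate_observations(params, profile, design)
  structure(list(name = name, params = params, profile = profile,
                 design = design, series = series),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %s sampling, %d samples, noise CV %.2g\n",
              x$name, x$design$schedule, length(x$design$sample_times),
              x$design$noise_cv))
  invisible(x)
}
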