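#' Stroboscopic (Poincare) map of the forced clock
#'
#' Advances a state on the section t = 0 (mod T) through `n` forcing periods.
#' Entrained oscillations are fixed points of this map; period-doubled
#' oscillations are fixed points of its iterates.
#'
#' @param state numeric length-3 state on the section.
#' @param params a [clock_params()] object.
#' @param profile a periodic [light_profile()].
#' @param n number of map applications.
#' @param step integration step (h).
#' @return if `n == 1`, the mapped state (length-3); otherwise an `n` x 3
#'   matrix of successive section states.
#' @export
stroboscopic_map <- function(state, params, profile, n = 1, step = 0.01) {
  stopifnot(inherits(profile, "light_profile"))
  m <- cpp_map_iterate(as.numeric(state), as_params_vec(params),
                       profile_vec(profile), as.integer(n), step)
  if (n == 1) as.numeric(m[1, ]) else m
}

#' Monodromy matrix of the stroboscopic map
#'
#' Jacobian of the time-T flow at `state`, obtained by integrating the
#' variational equations alongside the state. Forcing discontinuities occur
#' at state-independent times, so the variational system is integrated
#' segment-wise between breakpoints and segment Jacobians compose by matrix
#' product with no saltation correction. Its eigenvalues are the
#' characteristic (Floquet) multipliers of the associated periodic orbit.
#'
#' @inheritParams stroboscopic_map
#' @param t_len flow time (h); defaults to the profile period, or must be
#'   given for `profile = NULL` (constant darkness).
#' @return list with `state` (mapped state) and `monodromy` (3 x 3 matrix).
#' @export
monodromy <- function(state, params, profile = NULL, t_len = NULL, step = 0.01) {
  if (is.null(t_len)) {
    if (!inherits(profile, "light_profile"))
      stop("t_len must be given when profile is not a periodic light_profile")
    t_len <- profile$period
  }
  cpp_monodromy(as.numeric(state), as_params_vec(params), profile_vec(profile),
                0, t_len, step)
}

multipliers <- function(mono) eigen(mono$monodromy, only.values = TRUE)$values

real_multipliers <- function(mu) Re(mu[abs(Im(mu)) < 1e-4 * (1 + abs(mu))])

#' Locate an entrained orbit as a map fixed point
#'
#' Newton iteration on F(s) = map(s) - s, using the monodromy matrix as the
#' map Jacobian. When Newton diverges the routine falls back to long
#' brute-force map iteration (which can only find stable orbits). The
#' returned fixed point carries its characteristic multipliers; the orbit is
#' stable iff all multipliers lie inside the unit circle.
#'
#' @inheritParams stroboscopic_map
#' @param guess starting state; by default obtained by iterating the map 200
#'   times from (0.1, 0.1, 0.1).
#' @param tol Newton residual tolerance (nM, sup norm).
#' @param max_iter maximum Newton iterations.
#' @param fallback when Newton diverges, fall back to long brute-force map
#'   iteration (which can only reach stable orbits).
#' @return an object of class `map_fixed_point`: list with `state`,
#'   `multipliers` (complex length-3), `stable`, `residual`, `method`.
#'   Errors with "no stable fixed point reached" when brute-force iteration
#'   fails to converge (not entrained), distinguishable from Newton
#'   non-convergence on an unstable orbit.
#' @export
find_entrained_orbit <- function(params, profile, guess = NULL,
                                 tol = 1e-10, max_iter = 50, step = 0.01,
                                 fallback = TRUE) {
  stopifnot(inherits(profile, "light_profile"))
  par <- as_params_vec(params)
  pv <- profile_vec(profile)
  if (is.null(guess)) {
    it <- cpp_map_iterate(c(0.1, 0.1, 0.1), par, pv, 200L, step)
    guess <- as.numeric(it[200, ])
  }
  newton_from <- function(s) {
    mo <- cpp_monodromy(s, par, pv, 0, profile$period, step)
    f <- mo$state - s
    for (k in seq_len(max_iter)) {
      if (max(abs(f)) < tol)
        return(list(state = s, mono = mo$monodromy, residual = max(abs(f))))
      ds <- tryCatch(solve(mo$monodromy - diag(3), -f), error = function(e) NULL)
      if (is.null(ds) || any(!is.finite(ds))) return(NULL)
      # damped step: halve until the residual does not grow
      lam <- 1
      repeat {
        s_new <- s + lam * ds
        if (all(is.finite(s_new)) && all(s_new > -0.5) && max(abs(s_new)) < 1e3) {
          mo_new <- cpp_monodromy(s_new, par, pv, 0, profile$period, step)
          f_new <- mo_new$state - s_new
          if (max(abs(f_new)) <= max(abs(f)) || lam < 1 / 128) break
        } else if (lam < 1 / 128) return(NULL)
        lam <- lam / 2
      }
      if (!all(is.finite(s_new))) return(NULL)
      s <- s_new; mo <- mo_new; f <- f_new
    }
    NULL
  }
  res <- newton_from(as.numeric(guess))
  method <- "newton"
  if (is.null(res) && fallback) {
    # brute force in chunks with an early convergence exit
    s <- c(0.1, 0.1, 0.1)
    converged <- FALSE
    for (chunk in seq_len(20)) {
      it <- cpp_map_iterate(s, par, pv, 100L, step)
      s_new <- as.numeric(it[100, ])
      if (max(abs(s_new - as.numeric(it[99, ]))) < 1e-7) {
        converged <- TRUE
        s <- s_new
        break
      }
      s <- s_new
    }
    if (!converged)
      stop("no stable fixed point reached: map iterates do not converge ",
           "(not entrained 1:1, or unstable and not locatable by iteration)")
    res <- newton_from(s)
    method <- "brute_force+newton"
    if (is.null(res))
      stop("no convergence: Newton failed to polish the iterated state")
  }
  if (is.null(res))
    stop("no convergence: Newton iteration diverged from the supplied guess")
  mu <- eigen(res$mono, only.values = TRUE)$values
  structure(list(state = res$state, multipliers = mu,
                 stable = all(Mod(mu) < 1), residual = res$residual,
                 monodromy = res$mono, method = method, profile = profile),
            class = "map_fixed_point")
}

#' @export
print.map_fixed_point <- function(x, ...) {
  cat(sprintf("<map_fixed_point> %s (residual %.2e, %s)\n",
              if (x$stable) "stable" else "unstable", x$residual, x$method))
  cat(sprintf("  state: M=%.6f Pc=%.6f Pn=%.6f nM\n",
              x$state[1], x$state[2], x$state[3]))
  cat("  multipliers:", paste(format(round(x$multipliers, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Locate a bifurcation of the entrained orbit by bisection
#'
#' Marches a scalar family parameter across a bracket and bisects on a
#' multiplier test function: at a saddle-node (SN) a real multiplier crosses
#' +1 (on the far side the fixed point ceases to exist); at a period
#' doubling (PD) a real multiplier crosses -1; at a Neimark--Sacker (NS)
#' bifurcation a complex pair crosses the unit circle. Fixed points are
#' continued: each evaluation starts Newton from the nearest previously
#' converged fixed point.
#'
#' @param params a [clock_params()] object.
#' @param family function of one scalar returning a [light_profile()].
#' @param bracket numeric length-2 bracket for the scanned parameter; the
#'   test function must change sign across it.
#' @param type `"SN"`, `"PD"` or `"NS"`.
#' @param guess optional starting state for the first fixed point (taken at
#'   the bracket end where the orbit exists: upper end for SN, lower for PD).
#' @param tol bisection width tolerance in the scanned parameter.
#' @param step integration step (h).
#' @return an object of class `bifurcation_point`: list with `type`,
#'   `critical_value`, `fixed_point` (at the last converged side) and
#'   `multipliers`.
#' @export
locate_bifurcation <- function(params, family, bracket, type = c("SN", "PD", "NS"),
                               guess = NULL, tol = 1e-4, step = 0.01) {
  type <- match.arg(type)
  stopifnot(is.function(family), length(bracket) == 2, bracket[1] < bracket[2])
  state <- new.env()
  state$guess <- guess
  state$fp <- NULL
  test_fun <- function(cval) {
    prof <- family(cval)
    fp <- tryCatch(
      find_entrained_orbit(params, prof, guess = state$guess, step = step,
                           fallback = FALSE),
      error = function(e) NULL)
    if (is.null(fp)) {
      # fixed point not locatable: past the SN (orbit gone); for PD/NS the
      # orbit persists, so this signals a genuine failure
      if (type == "SN") return(list(f = 1, fp = NULL))
      stop("fixed point lost inside the bracket while locating a ", type,
           " bifurcation")
    }
    state$guess <- fp$state
    state$fp <- fp
    mu <- fp$multipliers
    f <- switch(type,
      SN = {
        rm_ <- real_multipliers(mu)
        if (!length(rm_)) 1 else max(rm_) - 1
      },
      PD = {
        rm_ <- real_multipliers(mu)
        if (!length(rm_)) stop("no real multiplier while locating PD")
        min(rm_) + 1
      },
      NS = {
        cp <- mu[abs(Im(mu)) >= 1e-4 * (1 + abs(mu))]
        if (!length(cp)) -1 else max(Mod(cp)) - 1
      })
    list(f = f, fp = fp)
  }
  # evaluate the "existing" side first so continuation guesses are sane
  ord <- if (type == "SN") c(2, 1) else c(1, 2)
  vals <- list()
  vals[[ord[1]]] <- test_fun(bracket[ord[1]])
  vals[[ord[2]]] <- test_fun(bracket[ord[2]])
  f_lo <- vals[[1]]$f; f_hi <- vals[[2]]$f
  if (sign(f_lo) == sign(f_hi))
    stop("no sign change: test function has the same sign at both bracket ends (",
         signif(f_lo, 4), ", ", signif(f_hi, 4), ")")
  lo <- bracket[1]; hi <- bracket[2]
  last_fp <- state$fp
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- test_fun(mid)
    if (!is.null(r$fp)) last_fp <- r$fp
    if (sign(r$f) == sign(f_lo)) {
      lo <- mid
    } else {
      hi <- mid; f_hi <- r$f
    }
  }
  crit <- (lo + hi) / 2
  structure(list(type = type, critical_value = crit, fixed_point = last_fp,
                 multipliers = last_fp$multipliers, bracket = c(lo, hi)),
            class = "bifurcation_point")
}

#' @export
print.bifurcation_point <- function(x, ...) {
  cat(sprintf("<bifurcation_point> %s at parameter = %.6g (bracket width %.2g)\n",
              x$type, x$critical_value, diff(x$bracket)))
  invisible(x)
}

# continuation march along X_max until the test multiplier event brackets;
# returns c(lo, hi) and leaves the env's guess at the last fixed point
march_to_bracket <- function(params, make_prof, x_start, direction,
                             event, x_limit, factor = 1.2, step = 0.01,
                             guess = NULL) {
  x <- x_start
  fp <- find_entrained_orbit(params, make_prof(x), guess = guess, step = step)
  ev_prev <- event(fp)
  x_prev <- x
  repeat {
    x_new <- if (direction > 0) x * factor else x / factor
    if ((direction > 0 && x_new > x_limit) || (direction < 0 && x_new < x_limit))
      x_new <- x_limit
    fp_new <- tryCatch(
      find_entrained_orbit(params, make_prof(x_new), guess = fp$state,
                           step = step, fallback = FALSE),
      error = function(e) NULL)
    ev_new <- if (is.null(fp_new)) NA else event(fp_new)
    if (is.na(ev_new) || sign(ev_new) != sign(ev_prev))
      return(list(bracket = sort(c(x_prev, x_new)), guess = fp$state))
    if (x_new == x_limit)
      stop("no bifurcation bracketed before X_max limit ", x_limit)
    x <- x_new
    x_prev <- x_new
    fp <- fp_new
    ev_prev <- ev_new
  }
}

#' Lower and upper entrainment limits in X^max
#'
#' For a fixed waveform shape, scans the maximum transcriptional response
#' X^max and locates the boundaries of 1:1 entrainment under 12:12 LD cycles:
#' the lower limit is a saddle-node bifurcation (onset of locking), the upper
#' a period-doubling bifurcation (loss of stability of the entrained orbit).
#'
#' @param params a [clock_params()] object.
#' @param t_s plateau duration T_s (h).
#' @param kind `"adaptation"` (decay fills the rest of the photoperiod,
#'   T_d = photoperiod - T_s) or `"slow_response"` (rise fills it,
#'   T_r = photoperiod - T_s); `t_d` can instead be fixed explicitly.
#' @param t_d fixed decay time; overrides the T_s + T_d = photoperiod
#'   constraint when given (adaptation only).
#' @param period,photoperiod LD cycle geometry (h).
#' @param x_seed an amplitude inside the entrained region used to seed
#'   continuation (default 0.4).
#' @param x_min,x_max scan limits for the bisections.
#' @param tol bisection tolerance in X^max.
#' @param step integration step (h).
#' @return list with `x_lower` (SN), `x_upper` (PD), and the two
#'   `bifurcation_point` objects (`sn`, `pd`).
#' @export
entrainment_limits <- function(params, t_s, kind = c("adaptation", "slow_response"),
                               t_d = NULL, period = 24, photoperiod = period / 2,
                               x_seed = 0.4, x_min = 1e-3, x_max = 100,
                               tol = 1e-4, step = 0.01) {
  kind <- match.arg(kind)
  make_prof <- function(x) {
    if (kind == "adaptation") {
      td <- if (is.null(t_d)) photoperiod - t_s else t_d
      light_profile("adaptation", x_max = x, t_s = t_s, t_d = td,
                    period = period, photoperiod = photoperiod)
    } else {
      light_profile("slow_response", x_max = x, t_s = t_s,
                    t_r = photoperiod - t_s, period = period,
                    photoperiod = photoperiod)
    }
  }
  ev_sn <- function(fp) max(real_multipliers(fp$multipliers)) - 1
  ev_pd <- function(fp) {
    rm_ <- real_multipliers(fp$multipliers)
    if (!length(rm_)) 1 else min(rm_) + 1
  }
  br_lo <- march_to_bracket(params, make_prof, x_seed, -1, ev_sn, x_min,
                            step = step)
  sn <- locate_bifurcation(params, make_prof, br_lo$bracket, "SN",
                           guess = br_lo$guess, tol = tol, step = step)
  br_hi <- march_to_bracket(params, make_prof, x_seed, +1, ev_pd, x_max,
                            step = step)
  pd <- locate_bifurcation(params, make_prof, br_hi$bracket, "PD",
                           guess = br_hi$guess, tol = tol, step = step)
  if (!(sn$critical_value < pd$critical_value))
    warning("lower (SN) limit is not below upper (PD) limit; check conditions")
  list(x_lower = sn$critical_value, x_upper = pd$critical_value, sn = sn, pd = pd)
}

#' Classify the attractor reached under periodic forcing
#'
#' Iterates the stroboscopic map past a transient, then inspects the sampled
#' section points: if the orbit repeats after k iterates (within `tol` in
#' every coordinate) the attractor is period-k (k = 1 is 1:1 entrainment);
#' otherwise the tangent-map Lyapunov exponent separates quasi-periodic
#' motion (exponent ~ 0, points filling a closed curve) from chaos
#' (positive exponent).
#'
#' @inheritParams stroboscopic_map
#' @param transient_cycles map iterates discarded (>= 200).
#' @param sample_cycles map iterates inspected.
#' @param tol distance tolerance (nM) for declaring a repeat.
#' @param max_period largest cycle length searched.
#' @param lyap_tol threshold for the per-iterate Lyapunov exponent.
#' @param init starting state.
#' @return an object of class `attractor_class`: list with `label` (one of
#'   `"entrained-1T"`, `"period-k"`, `"quasiperiodic"`, `"chaotic"`,
#'   `"undetermined"`), `period` (k, or NA), `lyapunov`, and the sampled
#'   section `points`.
#' @export
classify_attractor <- function(params, profile, transient_cycles = 500,
                               sample_cycles = 1000, tol = 1e-4,
                               max_period = 32, lyap_tol = 0.01,
                               init = c(0.1, 0.1, 0.1), step = 0.01) {
  stopifnot(inherits(profile, "light_profile"))
  if (transient_cycles < 200) stop("transient_cycles must be >= 200")
  res <- cpp_map_lyapunov(as.numeric(init), as_params_vec(params),
                          profile_vec(profile), as.integer(transient_cycles),
                          as.integer(sample_cycles), step)
  pts <- res$points
  n <- nrow(pts)
  period <- NA_integer_
  for (k in seq_len(min(max_period, n - 1))) {
    d <- abs(pts[seq_len(n - k), , drop = FALSE] - pts[(k + 1):n, , drop = FALSE])
    if (max(d) < tol) { period <- k; break }
  }
  lyap <- res$lyapunov
  label <- if (!is.na(period)) {
    if (period == 1) "entrained-1T" else paste0("period-", period)
  } else if (lyap > lyap_tol) {
    "chaotic"
  } else if (abs(lyap) <= lyap_tol) {
    "quasiperiodic"
  } else {
    "undetermined"  # negative exponent but no finite period found
  }
  structure(list(label = label, period = period, lyapunov = lyap,
                 points = pts, tol = tol),
            class = "attractor_class")
}

#' @export
print.attractor_class <- function(x, ...) {
  cat(sprintf("<attractor_class> %s (Lyapunov exponent %.4f per iterate%s)\n",
              x$label, x$lyapunov,
              if (!is.na(x$period)) sprintf(", period %d", x$period) else ""))
  invisible(x)
}

#' One-parameter bifurcation diagram over X^max
#'
#' For each amplitude in `x_grid`, iterates the stroboscopic map and records
#' the post-transient section values of M: a single value signals 1:1
#' entrainment, 2^k values a period-doubled orbit, and a band quasi-periodic
#' or chaotic motion.
#'
#' @inheritParams classify_attractor
#' @param x_grid amplitudes X^max to scan.
#' @param t_s,t_d waveform durations (h), adaptation shape.
#' @param period,photoperiod LD cycle geometry (h).
#' @param keep section points recorded per amplitude.
#' @return data frame with columns `X_max` and `M_section`.
#' @export
one_parameter_diagram <- function(params, x_grid, t_s = 6, t_d = 6,
                                  period = 24, photoperiod = period / 2,
                                  transient_cycles = 300, keep = 64,
                                  step = 0.01) {
  rows <- lapply(x_grid, function(x) {
    prof <- light_profile("adaptation", x_max = x, t_s = t_s, t_d = t_d,
                          period = period, photoperiod = photoperiod)
    it <- cpp_map_iterate(c(0.1, 0.1, 0.1), as_params_vec(params),
                          profile_vec(prof),
                          as.integer(transient_cycles + keep), step)
    m <- it[(transient_cycles + 1):(transient_cycles + keep), 1]
    data.frame(X_max = x, M_section = m)
  })
  do.call(rbind, rows)
}

#' Two-parameter bifurcation scan over (X^max, T)
#'
#' For each forcing period T on the grid, locates the saddle-node and
#' period-doubling limits in X^max with the waveform durations scaled with T
#' (adaptation: T_s = 3T/24, T_d = 9T/24; slow response: T_r = 9T/24,
#' T_s = 3T/24). While marching upward the complex-pair modulus is monitored,
#' and a Neimark--Sacker point is reported where a non-real pair crosses the
#' unit circle before any real multiplier reaches -1. Assembled per-T points
#' trace out the Arnold-tongue boundaries around T = tau.
#'
#' @param params a [clock_params()] object.
#' @param T_grid forcing periods (h).
#' @param kind waveform family.
#' @param x_seed,x_min,x_max,tol,step as in [entrainment_limits()].
#' @return data frame with columns `T_h`, `type` (`"SN"`, `"PD"`, `"NS"`),
#'   `X_crit`. Cells where a boundary could not be located are dropped with
#'   a warning.
#' @export
two_parameter_scan <- function(params, T_grid, kind = c("adaptation", "slow_response"),
                               x_seed = 0.4, x_min = 1e-3, x_max = 100,
                               tol = 1e-4, step = 0.01) {
  kind <- match.arg(kind)
  out <- list()
  for (TT in T_grid) {
    make_prof <- function(x) {
      if (kind == "adaptation")
        light_profile("adaptation", x_max = x, t_s = 3 * TT / 24,
                      t_d = 9 * TT / 24, period = TT)
      else
        light_profile("slow_response", x_max = x, t_s = 3 * TT / 24,
                      t_r = 9 * TT / 24, period = TT)
    }
    ev_sn <- function(fp) max(real_multipliers(fp$multipliers)) - 1
    ev_pd <- function(fp) {
      rm_ <- real_multipliers(fp$multipliers)
      if (!length(rm_)) 1 else min(rm_) + 1
    }
    ev_ns <- function(fp) {
      mu <- fp$multipliers
      cp <- mu[abs(Im(mu)) >= 1e-4 * (1 + abs(mu))]
      if (!length(cp)) -1 else max(Mod(cp)) - 1
    }
    cell <- function(type, event, direction, lim) {
      tryCatch({
        br <- march_to_bracket(params, make_prof, x_seed, direction, event,
                               lim, step = step)
        bp <- locate_bifurcation(params, make_prof, br$bracket, type,
                                 guess = br$guess, tol = tol, step = step)
        data.frame(T_h = TT, type = type, X_crit = bp$critical_value)
      }, error = function(e) {
        warning("T = ", TT, ", ", type, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    }
    out[[length(out) + 1]] <- cell("SN", ev_sn, -1, x_min)
    # upward: report NS if a complex pair exits the unit circle before PD
    up <- tryCatch({
      br_ns <- tryCatch(
        march_to_bracket(params, make_prof, x_seed, +1, ev_ns, x_max, step = step),
        error = function(e) NULL)
      br_pd <- tryCatch(
        march_to_bracket(params, make_prof, x_seed, +1, ev_pd, x_max, step = step),
        error = function(e) NULL)
      pick_ns <- !is.null(br_ns) &&
        (is.null(br_pd) || br_ns$bracket[2] <= br_pd$bracket[2])
      if (pick_ns) {
        bp <- locate_bifurcation(params, make_prof, br_ns$bracket, "NS",
                                 guess = br_ns$guess, tol = tol, step = step)
        data.frame(T_h = TT, type = "NS", X_crit = bp$critical_value)
      } else if (!is.null(br_pd)) {
        bp <- locate_bifurcation(params, make_prof, br_pd$bracket, "PD",
                                 guess = br_pd$guess, tol = tol, step = step)
        data.frame(T_h = TT, type = "PD", X_crit = bp$critical_value)
      } else NULL
    }, error = function(e) {
      warning("T = ", TT, ", upper boundary: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    out[[length(out) + 1]] <- up
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no bifurcation points located on the grid")
  res
}
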