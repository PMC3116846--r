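#' Transcriptional light-response profiles
#'
#' Builds the piecewise-linear waveform X(t) describing how light up-regulates
#' transcription across a light--dark (LD) cycle. Three shapes are supported:
#'
#' * `"adaptation"`: X jumps to `x_max` at lights-on, stays there for `t_s`
#'   hours, then decays linearly to zero over `t_d` hours (transient light
#'   induction, as for Neurospora frq or mouse Per1).
#' * `"slow_response"`: X ramps linearly from zero over `t_r` hours, plateaus
#'   at `x_max` for `t_s` hours, and drops to zero exactly at the light--dark
#'   transition (as for mouse Per2). The plateau must end at lights-off, so
#'   `t_r + t_s` must equal the photoperiod.
#' * `"square"`: constant `x_max` through the whole light phase (adaptation
#'   with `t_s = photoperiod`, `t_d = 0`).
#' * `"none"`: no forcing (constant darkness).
#'
#' Segments are half-open `[start, end)` so X is right-continuous; the value
#' exactly at the light--dark transition is the dark value (0). Lights-on is
#' at t = 0 (mod `period`).
#'
#' @param kind one of `"adaptation"`, `"slow_response"`, `"square"`, `"none"`.
#' @param x_max maximum transcriptional response X^max (dimensionless >= 0).
#' @param t_s plateau duration (h).
#' @param t_d decay duration (h; adaptation only).
#' @param t_r rise duration (h; slow_response only).
#' @param period forcing period T of the LD cycle (h).
#' @param photoperiod light-phase length (h); defaults to `period / 2` (12:12).
#' @return an object of class `light_profile`.
#' @examples
#' light_profile("adaptation", x_max = 1.5, t_s = 6, t_d = 6)
#' light_profile("square", x_max = 0.75)
#' @export
light_profile <- function(kind = c("adaptation", "slow_response", "square", "none"),
                          x_max = 1, t_s = 0, t_d = 0, t_r = 0,
                          period = 24, photoperiod = period / 2) {
  kind <- match.arg(kind)
  if (!is.finite(period) || period <= 0) stop("period must be positive")
  if (!is.finite(photoperiod) || photoperiod <= 0 || photoperiod > period)
    stop("photoperiod must lie in (0, period]")
  if (!is.finite(x_max) || x_max < 0) stop("x_max must be >= 0")
  if (kind == "square") {
    kind <- "adaptation"
    t_s <- photoperiod
    t_d <- 0
  }
  if (kind == "none" || x_max == 0) {
    return(structure(list(kind = "none", x_max = 0, t_s = 0, t_d = 0, t_r = 0,
                          period = period, photoperiod = photoperiod),
                     class = "light_profile"))
  }
  if (any(c(t_s, t_d, t_r) < 0)) stop("durations must be >= 0")
  if (kind == "adaptation") {
    if (t_s + t_d > photoperiod + 1e-9)
      stop("adaptation profile requires T_s + T_d <= photoperiod (got ",
           t_s, " + ", t_d, " > ", photoperiod, ")")
    t_r <- 0
  } else {
    if (abs(t_r + t_s - photoperiod) > 1e-9)
      stop("slow_response profile requires T_r + T_s = photoperiod ",
           "(the plateau ends at the light-dark transition); got ",
           t_r, " + ", t_s, " != ", photoperiod)
    t_d <- 0
  }
  structure(list(kind = kind, x_max = x_max, t_s = t_s, t_d = t_d, t_r = t_r,
                 period = period, photoperiod = photoperiod),
            class = "light_profile")
}

#' Single light pulse
#'
#' A one-shot version of a [light_profile()] waveform, applied once starting
#' at a chosen phase of the free-running cycle (used for phase response
#' curves). A `"square"` pulse of the default 12-h duration is the
#' rectangular pulse used in PRC experiments.
#'
#' @inheritParams light_profile
#' @param duration pulse duration (h); the waveform is zero outside
#'   `[0, duration)`.
#' @return an object of class `light_pulse`.
#' @examples
#' light_pulse("square", x_max = 0.75)              # 12-h rectangular pulse
#' light_pulse("adaptation", x_max = 0.75, t_s = 9, t_d = 3)
#' @export
light_pulse <- function(kind = c("adaptation", "slow_response", "square", "none"),
                        x_max = 1, t_s = 0, t_d = 0, t_r = 0, duration = 12) {
  kind <- match.arg(kind)
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(x_max) || x_max < 0) stop("x_max must be >= 0")
  if (kind == "square") {
    kind <- "adaptation"
    t_s <- duration
    t_d <- 0
  }
  if (kind != "none") {
    if (any(c(t_s, t_d, t_r) < 0)) stop("durations must be >= 0")
    shape_len <- if (kind == "adaptation") t_s + t_d else t_r + t_s
    if (shape_len > duration + 1e-9)
      stop("waveform (", shape_len, " h) does not fit in pulse duration (",
           duration, " h)")
  }
  structure(list(kind = kind, x_max = if (kind == "none") 0 else x_max,
                 t_s = t_s, t_d = t_d, t_r = t_r, duration = duration),
            class = "light_pulse")
}

#' @export
print.light_profile <- function(x, ...) {
  cat(sprintf("<light_profile> kind=%s X_max=%g T_s=%g T_d=%g T_r=%g T=%g photoperiod=%g\n",
              x$kind, x$x_max, x$t_s, x$t_d, x$t_r, x$period, x$photoperiod))
  invisible(x)
}

#' @export
print.light_pulse <- function(x, ...) {
  cat(sprintf("<light_pulse> kind=%s X_max=%g T_s=%g T_d=%g T_r=%g duration=%g\n",
              x$kind, x$x_max, x$t_s, x$t_d, x$t_r, x$duration))
  invisible(x)
}

kind_code <- function(kind) switch(kind, none = 0, adaptation = 1, slow_response = 2)

# encode a profile/pulse (or NULL = DD) for the compiled core
profile_vec <- function(profile, pulse_start = 0) {
  if (is.null(profile))
    return(c(kind = 0, mode = 0, X_max = 0, T_s = 0, T_d = 0, T_r = 0,
             T = 24, photoperiod = 12, pulse_start = 0, pulse_dur = 0))
  if (inherits(profile, "light_profile")) {
    mode <- if (profile$kind == "none") 0 else 1
    return(c(kind = kind_code(profile$kind), mode = mode,
             X_max = profile$x_max, T_s = profile$t_s, T_d = profile$t_d,
             T_r = profile$t_r, T = profile$period,
             photoperiod = profile$photoperiod, pulse_start = 0, pulse_dur = 0))
  }
  if (inherits(profile, "light_pulse")) {
    mode <- if (profile$kind == "none") 0 else 2
    return(c(kind = kind_code(profile$kind), mode = mode,
             X_max = profile$x_max, T_s = profile$t_s, T_d = profile$t_d,
             T_r = profile$t_r, T = profile$duration,
             photoperiod = profile$duration, pulse_start = pulse_start,
             pulse_dur = profile$duration))
  }
  stop("profile must be a light_profile, light_pulse, or NULL")
}

#' Evaluate the light response X(t)
#'
#' For a periodic [light_profile()], `t` is absolute time with lights-on at
#' t = 0 (mod T) and the waveform repeats with period T. For a
#' [light_pulse()], `t` is time since pulse onset and the response is zero
#' outside `[0, duration)`.
#'
#' @param profile a `light_profile` or `light_pulse`.
#' @param t time(s) in hours (vectorized).
#' @return the dimensionless response X at each `t`.
#' @examples
#' p <- light_profile("adaptation", x_max = 1, t_s = 6, t_d = 6)
#' light_value(p, c(3, 9, 15))  # plateau, mid-decay, dark
#' @export
light_value <- function(profile, t) {
  if (any(!is.finite(t))) stop("t must be finite")
  pv <- profile_vec(profile)
  vapply(t, function(ti) cpp_light_value(pv, ti), numeric(1))
}

#' Serialize / deserialize light profiles
#'
#' Round-trips a profile through a plain named list (suitable for JSON/YAML
#' configs): fields `kind, X_max, T_s, T_d, T_r, T, photoperiod`.
#'
#' @param profile a `light_profile`.
#' @param config a named list as produced by `profile_to_config()`.
#' @return `profile_to_config()` returns a named list; `profile_from_config()`
#'   a `light_profile`.
#' @export
profile_to_config <- function(profile) {
  stopifnot(inherits(profile, "light_profile"))
  list(kind = profile$kind, X_max = profile$x_max, T_s = profile$t_s,
       T_d = profile$t_d, T_r = profile$t_r, T = profile$period,
       photoperiod = profile$photoperiod)
}

#' @rdname profile_to_config
#' @export
profile_from_config <- function(config) {
  light_profile(kind = config$kind, x_max = config$X_max, t_s = config$T_s,
                t_d = config$T_d, t_r = config$T_r, period = config$T,
                photoperiod = config$photoperiod)
}
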