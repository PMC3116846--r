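#' Kinetic parameters of the three-variable clock model
#'
#' Constructs the parameter set of the minimal negative-feedback oscillator:
#' transcription of clock mRNA repressed by nuclear protein through a Hill
#' term, Michaelis--Menten degradation of mRNA and cytosolic protein, linear
#' translation and nuclear import/export.
#'
#' Two named sets ship with the package. `"neurospora_21p5h"` is the default
#' wild-type set (free-running period 21.5 h under constant darkness, matching
#' the endogenous Neurospora period): n = 4, K_I = 1 nM, v_s = 1.6 nM/h,
#' v_m = 0.505 nM/h, K_M = 0.5 nM, k_s = 0.5 /h, v_d = 1.4 nM/h,
#' K_d = 0.13 nM, k_1 = 0.5 /h, k_2 = 0.6 /h. `"mammal_25h"` is the same set
#' with v_s = 2.5 nM/h, giving a 25-h period typical of mammals.
#'
#' @param set name of a shipped parameter set, or `NULL` to use
#'   `"neurospora_21p5h"` as the base.
#' @param ... individual parameter overrides by symbol name (`n`, `K_I`,
#'   `v_s`, `v_m`, `K_M`, `k_s`, `v_d`, `K_d`, `k_1`, `k_2`).
#' @return an object of class `clock_params`: a named numeric vector of the
#'   ten kinetic constants.
#' @examples
#' p <- clock_params()                    # Neurospora-like, 21.5 h
#' p25 <- clock_params("mammal_25h")      # v_s = 2.5 nM/h, 25 h
#' p2 <- clock_params(v_s = 2.0)          # override one constant
#' @export
clock_params <- function(set = "neurospora_21p5h", ...) {
  sets <- list(
    neurospora_21p5h = c(n = 4, K_I = 1, v_s = 1.6, v_m = 0.505, K_M = 0.5,
                         k_s = 0.5, v_d = 1.4, K_d = 0.13, k_1 = 0.5, k_2 = 0.6),
    mammal_25h = c(n = 4, K_I = 1, v_s = 2.5, v_m = 0.505, K_M = 0.5,
                   k_s = 0.5, v_d = 1.4, K_d = 0.13, k_1 = 0.5, k_2 = 0.6)
  )
  if (is.null(set)) set <- "neurospora_21p5h"
  if (!set %in% names(sets))
    stop("unknown parameter set '", set, "'; available: ",
         paste(names(sets), collapse = ", "))
  p <- sets[[set]]
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- unlist(ov)
  }
  validate_clock_params(p)
  structure(p, class = "clock_params")
}

validate_clock_params <- function(p) {
  req <- c("n", "K_I", "v_s", "v_m", "K_M", "k_s", "v_d", "K_d", "k_1", "k_2")
  if (!all(req %in% names(p)))
    stop("missing parameter(s): ", paste(setdiff(req, names(p)), collapse = ", "))
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all kinetic parameters must be finite and strictly positive")
  if (p[["n"]] < 1) stop("Hill coefficient n must be >= 1")
  invisible(p)
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<clock_params> three-variable negative-feedback clock model\n")
  print(unclass(x), ...)
  invisible(x)
}

as_params_vec <- function(params) {
  if (inherits(params, "clock_params")) return(unclass(params))
  validate_clock_params(params)
  params
}

#' Instantaneous rates of the clock vector field
#'
#' Evaluates the right-hand side of the model at one state:
#' \deqn{dM/dt = v_s (1 + X) K_I^n / (K_I^n + P_N^n) - v_m M / (K_M + M)}
#' \deqn{dP_C/dt = k_s M - v_d P_C / (K_d + P_C) - k_1 P_C + k_2 P_N}
#' \deqn{dP_N/dt = k_1 P_C - k_2 P_N}
#' The transcriptional light response `x_light` scales only the synthesis
#' term, through the factor (1 + X).
#'
#' @param state numeric length-3: concentrations (M, P_C, P_N) in nM.
#' @param params a [clock_params()] object.
#' @param x_light dimensionless transcriptional response X (>= 0).
#' @return numeric length-3 of derivatives (nM/h), named `M`, `P_C`, `P_N`.
#' @examples
#' clock_field(c(0, 0, 0), clock_params())  # only unrepressed synthesis: 1.6 nM/h
#' @export
clock_field <- function(state, params = clock_params(), x_light = 0) {
  state <- as.numeric(state)
  if (length(state) != 3 || any(!is.finite(state)))
    stop("state must be three finite concentrations (M, P_C, P_N)")
  if (any(state < 0)) stop("negative concentrations are not allowed")
  if (!is.finite(x_light) || x_light < 0) stop("x_light must be finite and >= 0")
  d <- cpp_rhs(state, as_params_vec(params), x_light)
  names(d) <- c("M", "P_C", "P_N")
  d
}
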