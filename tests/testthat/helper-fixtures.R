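# shared, lazily computed fixtures (expensive objects built once per run)
.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

default_params <- clock_params()

lc_default <- function() fx("lc_default", find_limit_cycle(default_params))

prc_square <- function(x_max) {
  fx(paste0("prc_square_", x_max),
     compute_prc(default_params, light_pulse("square", x_max = x_max),
                 lc = lc_default()))
}

square_limits <- function() {
  fx("square_limits",
     entrainment_limits(default_params, t_s = 12, kind = "adaptation", t_d = 0))
}
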