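#' Experiment configuration
#'
#' A named, serializable bundle of the options for one reproducible
#' experiment. Known experiments: `"free_period_scan"`, `"entrainment_map"`
#' (boundary curves over a T_s grid), `"prc_suite"` (PRC CSVs over a set of
#' amplitudes), `"bifdiag_1d"` (one-parameter diagram over X^max),
#' `"classify"` (attractor label for one condition), and `"estimate_vs"`
#' (synthetic scenario through the estimation stage).
#'
#' @param experiment experiment name.
#' @param parameter_set parameter set name for [clock_params()].
#' @param seed integer seed (propagated to any stochastic component).
#' @param ... experiment-specific options (grids, waveform settings,
#'   tolerances); see the corresponding analysis functions for defaults.
#' @return an object of class `experiment_config` (a plain list; round-trips
#'   through JSON).
#' @export
experiment_config <- function(experiment, parameter_set = "neurospora_21p5h",
                              seed = 1, ...) {
  structure(c(list(experiment = experiment, parameter_set = parameter_set,
                   seed = as.integer(seed)), list(...)),
            class = "experiment_config")
}

cfg_get <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

#' Run a named experiment
#'
#' Executes the experiment described by an [experiment_config()], writes its
#' artifacts (CSV tables, JSON summaries) into `out_dir`, and returns a
#' manifest listing every file with its MD5 checksum plus a summary. Outputs
#' are deterministic given the config and seed. Per-task failures are
#' recorded in the manifest's `status` rather than aborting the run.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (data frame `file`, `md5`), `summary`, and
#'   `status` (`"ok"` or a per-task error message).
#' @export
run_experiment <- function(config, out_dir = tempfile("experiment")) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- clock_params(config$parameter_set)
  files <- character(0)
  summary <- list(experiment = config$experiment, seed = config$seed)
  status <- "ok"
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
    path
  }
  res <- tryCatch({
    switch(config$experiment,
      free_period_scan = {
        grid <- cfg_get(config, "vs_grid", c(1.3, 1.6, 2.5, 3.2))
        tab <- period_scan(params, grid)
        emit_csv(tab, "periods.csv")
        summary$periods <- tab$period_h
      },
      entrainment_map = {
        ts_grid <- cfg_get(config, "ts_grid", 0:12)
        kind <- cfg_get(config, "kind", "adaptation")
        rows <- lapply(ts_grid, function(ts) {
          lim <- entrainment_limits(params, t_s = ts, kind = kind,
                                    tol = cfg_get(config, "tol", 1e-4))
          data.frame(Ts_h = ts, Td_h = 12 - ts, X_lower_SN = lim$x_lower,
                     X_upper_PD = lim$x_upper)
        })
        tab <- do.call(rbind, rows)
        emit_csv(tab, "boundaries.csv")
        summary$n_rows <- nrow(tab)
      },
      prc_suite = {
        amps <- cfg_get(config, "amplitudes", c(0.125, 0.2, 0.75))
        lc <- find_limit_cycle(params)
        grid <- cfg_get(config, "phase_grid",
                        seq(0, lc$period - 1e-9, by = 0.25))
        mins <- vapply(amps, function(a) {
          pr <- compute_prc(params, light_pulse("square", x_max = a),
                            phase_grid = grid, lc = lc)
          emit_csv(data.frame(phase_h = pr$phases, shift_h = pr$shifts),
                   sprintf("prc_xmax_%g.csv", a))
          min(pr$shifts)
        }, numeric(1))
        summary$min_shifts <- as.list(stats::setNames(mins, paste0("X", amps)))
      },
      bifdiag_1d = {
        xg <- cfg_get(config, "x_grid", exp(seq(log(0.05), log(4), length.out = 40)))
        tab <- one_parameter_diagram(params, xg,
                                     t_s = cfg_get(config, "t_s", 6),
                                     t_d = cfg_get(config, "t_d", 6),
                                     transient_cycles = cfg_get(config, "transient", 300),
                                     keep = cfg_get(config, "keep", 32))
        emit_csv(tab, "bifdiag_1d.csv")
        summary$n_amplitudes <- length(xg)
      },
      classify = {
        prof <- profile_from_config(config$profile)
        cl <- classify_attractor(params, prof,
                                 transient_cycles = cfg_get(config, "transient", 500),
                                 sample_cycles = cfg_get(config, "samples", 1000))
        emit_csv(data.frame(Ts_h = prof$t_s, Td_h = prof$t_d,
                            Xmax = prof$x_max, label = cl$label),
                 "classification.csv")
        summary$label <- cl$label
        summary$lyapunov <- cl$lyapunov
      },
      estimate_vs = {
        sc <- clock_scenario(cfg_get(config, "preset", "neurospora_frq_LD"),
                             noise_cv = cfg_get(config, "noise_cv", 0),
                             seed = config$seed)
        est <- estimate_response(sc$series, sc$params,
                                 scales = attr(sc$series, "scales_true"))
        emit_csv(est$grid[, c("time_h", "vs_nM_per_h", "X")], "estimated_vs.csv")
        summary$shape_label <- est$shape$label
        summary$vs_dark <- est$vs_dark
      },
      stop("unknown experiment '", config$experiment, "'")
    )
    TRUE
  }, error = function(e) {
    status <<- conditionMessage(e)
    FALSE
  })
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, summary_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  list(manifest = manifest, summary = summary, status = status,
       out_dir = out_dir, ok = isTRUE(res))
}
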