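#' Default pipeline configuration
#'
#' All downstream stages take their tunable parameters from this list. The
#' defaults are the study's processing choices: 5 Hz fourth-order zero-phase
#' Butterworth low-pass, five equidistant evaluation points, four captures
#' per static trial, four extracted cycles, phases at 0/25/50/75/100 percent.
#'
#' @param ... Named overrides of individual fields.
#' @return A `pipeline_config` list with fields `cutoff_hz`, `filter_order`,
#'   `n_eval_points`, `n_static_captures`, `n_cycles_extracted`,
#'   `phase_percents`, `max_gap_frames`, `steady_tol_deg`,
#'   `prominence_frac`, `ml_pair` (`"side_midpoints"` or `"tip"`),
#'   `shared_eval_range`, `collinear_tol_mm`, `models`, `seed`.
#' @export
default_config <- function(...) {
  cfg <- list(
    cutoff_hz = 5,
    filter_order = 4,
    n_eval_points = 5L,
    n_static_captures = 4L,
    n_cycles_extracted = 4L,
    phase_percents = c(0, 25, 50, 75, 100),
    max_gap_frames = 24L,
    steady_tol_deg = 2,
    prominence_frac = 0.25,
    ml_pair = "side_midpoints",
    shared_eval_range = TRUE,
    collinear_tol_mm = 1e-6,
    models = spine_model_specs(),
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   invisibly returns `path`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$models <- NULL                       # model definitions are fixed code
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$models <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}
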