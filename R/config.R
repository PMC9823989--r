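#' Default run configuration
#'
#' One flat document holding every tunable decision parameter of the
#' pipeline, so unstated-in-the-literature constants are visible and
#' overridable in one place. Unknown keys in a user file are rejected.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(
    list(
      # beat cleaning
      wide_ms = 2000, narrow_ms = 350, irregular_tol = 0.2,
      # spectra
      tachogram_fs = 4, welch_segment_s = 128,
      # recognizers / smoothing
      small_frame = 11, large_frame = 121, sg_order = 2,
      k_min = -2, k_max = 2, k_grid_n = 41, band_grid_n = 15,
      c_h = 0.25, c_w = 0.5,
      # fusion classifiers
      n_keep = 15, max_rows = 3000,
      # post-hoc corrections
      rem_lockout_min = 80, deep_lockout_min = 30,
      # synthetic cohort
      night_hours = 8, n_subjects = 40, frac_poor = 0.35, artifact_rate = 0.01,
      # reproducibility
      seed = 1
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file of overrides; keys must exist in
#'   [default_config()].
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  base <- default_config()
  if (is.null(path)) {
    return(base)
  }
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- modifyList(unclass(base), user)
  structure(out, class = "run_config")
}

#' Digest of a resolved configuration
#'
#' @param config A `run_config`.
#' @return An md5 hex string identifying the configuration.
#' @export
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config)[order(names(config))], tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

control_from_config <- function(config) {
  stager_control(
    small_frame = config$small_frame, large_frame = config$large_frame,
    sg_order = config$sg_order,
    k_grid = seq(config$k_min, config$k_max, length.out = config$k_grid_n),
    band_grid = seq(config$k_min, config$k_max, length.out = config$band_grid_n),
    c_h = config$c_h, c_w = config$c_w,
    n_keep = config$n_keep, max_rows = config$max_rows,
    seed = config$seed
  )
}
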