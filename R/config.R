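#' Default scoring configuration
#'
#' All tunable parameters of the pipeline in one nested list:
#' time-frequency decomposition (`f_min`, `f_max`, `n_freqs`, `c_min`,
#' `c_max`, `hop_s`, `db_floor`, `db_mode`), epoching (`epoch_len_s`, 30
#' by default; >= 10 s remains usable), noise detection (`z_thresh`,
#' `rms_window_s`), display (`line_band`, `smooth_window_s`), band edges
#' (`bands`), peak refinement (`refine`, `spindle_search`, `rem_search`),
#' HMM fitting (`hmm`: `max_iter`, `tol`, `var_floor`, `sticky`,
#' `pi_wake`) and the correction rules (`correct`, `thresholds`).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    f_min = 0.1, f_max = 100, n_freqs = 100, c_min = 3, c_max = 30,
    hop_s = 0.5, db_floor = 1e-12, db_mode = "power",
    epoch_len_s = 30,
    z_thresh = 4, rms_window_s = 2,
    line_band = c(50, 70), smooth_window_s = 40,
    bands = list(wake = c(40, 95), rem = c(17, 26), light = c(11, 15.5),
                 hideep = c(1, 3), lodeep = c(0.1, 1)),
    refine = TRUE, spindle_search = c(9, 16), rem_search = c(15, 30),
    hmm = list(max_iter = 50, tol = 1e-6, var_floor = 0.25, sticky = 5,
               pi_wake = 0.6),
    correct = TRUE,
    thresholds = correction_thresholds())
}

#' Load a configuration YAML, merged over the defaults
#'
#' Keys present in the file override the corresponding defaults;
#' omitted keys keep their default values. Unknown top-level keys are
#' an error, so typos do not silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Config list as [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, y)
}
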