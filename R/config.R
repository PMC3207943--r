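# Run configuration: YAML/JSON files with defaults, validation and
# round-tripping.  Every stochastic entry point takes an explicit seed so a
# run is reproducible from its config alone.

.configDefaults <- function() {
  list(
    experiment = "neural-sampling",
    seed = 1L,
    out_dir = ".",
    sampler = list(tau = 20L, dt = 1, n_sweeps = 10000L, burn_in = 1000L,
                   update_order = "fixed", mechanism = "absolute",
                   psp_mode = "rect"),
    activation = list(u_min = -10, u_max = 10, u_step = 0.01, tol = 1e-10,
                      profile = "moderate"),
    evaluation = list(K = 10L, sigma_w = c(0.03, 0.3, 3.0), n_dists = 20L,
                      n_samples = 1e5, pseudo_count = 1,
                      mu_b = -1.5, sigma_b = 0.5),
    rivalry = list(layers = 5L, connection_radius = 4,
                   tuning = list(base = 0.03, contrast = 0.8, peak = 2),
                   n_patterns = 2e4, free_steps = 50L, learning_rate = 0.01,
                   duration_ms = 6e4)
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be a mapping")
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON; JSON is valid YAML) configuration file, validates
#' it against the known schema, and fills unset fields with defaults.  An
#' empty file yields the all-defaults configuration; unknown keys are
#' rejected with the offending key named.
#'
#' @param path configuration file, or NULL for pure defaults.
#' @return nested configuration list.
#' @export
loadConfig <- function(path = NULL) {
  defaults <- .configDefaults()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  .mergeConfig(defaults, user)
}

#' Write a configuration to YAML
#'
#' @param config configuration list.
#' @param path output file.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
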