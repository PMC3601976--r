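# Pipeline configuration: one nested list with documented defaults,
# optionally overridden from a YAML file.  All randomness flows from
# config$seed through named substreams.

#' Default pipeline configuration
#'
#' @param seed master seed for the whole pipeline.
#' @return nested configuration list with components `scenario` (see
#'   [sim_scenario()]), `screen` (see [screen_thresholds()]), `search`,
#'   `phylo`, `expression`.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scenario = sim_scenario(seed = seed),
    screen = screen_thresholds(),
    search = list(seed_k = 5L),
    phylo = list(n_bootstrap = 200L, rell_reps = 1000L,
                 calibration_age = 39, calibration_sd = 2.4),
    expression = list(read_length = 50L,
                      mapping_library_size = 2000L,
                      deep_library_size = 800000L,
                      n_flat_background = 200L,
                      flat_rpkm = 100))
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file; top-level keys mirror [default_config()].
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  user <- yaml::read_yaml(path)
  seed <- user$seed %||% 1L
  cfg <- default_config(seed = seed)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_lists(base[[k]], over[[k]])
      } else over[[k]]
    }
    base
  }
  cfg <- merge_lists(cfg, user)
  scen_args <- cfg$scenario[intersect(names(cfg$scenario),
                                      names(formals(sim_scenario)))]
  if (!is.null(scen_args$omega_classes)) {
    scen_args$omega_classes <- as.data.frame(scen_args$omega_classes)
  }
  if (!is.null(scen_args$pi)) scen_args$pi <- unlist(scen_args$pi)
  if (!is.null(scen_args$expression_profile)) {
    scen_args$expression_profile <- unlist(scen_args$expression_profile)
  }
  cfg$scenario <- do.call(sim_scenario, scen_args)
  cfg
}
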