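#' Run configuration
#'
#' Bundles the numerical conventions used across the pipeline: temperature,
#' the Boltzmann constant in kcal/(mol K), the switching-function reference
#' distances d0 for hydrogen bonds (3.5 A) and salt bridges (4 A), the grid
#' of imposed CV averages, the reference state (the zero of free energy,
#' default s = 14) and the random seed.
#'
#' @param temperature K, > 0.
#' @param kB Boltzmann constant, kcal/(mol K).
#' @param d0_hbond,d0_saltbridge switching-function reference distances (A).
#' @param cv_grid non-empty numeric vector of target imposed averages s.
#' @param reference_s the s at which the free energy is set to zero.
#' @param seed integer random seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperature = 300, kB = 0.0019872041,
                       d0_hbond = 3.5, d0_saltbridge = 4.0,
                       cv_grid = 2:14, reference_s = 14, seed = 1L) {
  if (temperature <= 0) stopf("temperature must be > 0")
  if (!length(cv_grid)) stopf("cv_grid must be non-empty")
  structure(list(temperature = temperature, kB = kB, d0_hbond = d0_hbond,
                 d0_saltbridge = d0_saltbridge, cv_grid = sort(cv_grid),
                 reference_s = reference_s, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}
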