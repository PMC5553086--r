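#' Read a simulation scenario from a YAML config file
#'
#' A scenario file names a preset and optionally overrides its parameters:
#' \preformatted{
#' preset: low_maf_ld        # null | main_effects | low_maf_ld |
#'                           # rare_ld_complex | complex_common
#' label: low-maf-ld-benchmark
#' params:
#'   maf: 0.1
#'   target_r2: 0.24
#'   replicates: 1000
#'   seed: 1
#' }
#' Example files ship under `system.file("extdata", "scenarios",
#' package = "wpair")`.
#'
#' @param path YAML file path.
#' @return A `scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$preset)) stop(path, ": missing 'preset' field")
  fn <- switch(cfg$preset,
               null = scenario_null,
               main_effects = scenario_main_effects,
               low_maf_ld = scenario_low_maf_ld,
               rare_ld_complex = scenario_rare_ld_complex,
               complex_common = scenario_complex_common,
               stop(path, ": unknown preset '", cfg$preset, "'"))
  params <- if (is.null(cfg$params)) list() else cfg$params
  scen <- do.call(fn, params)
  if (!is.null(cfg$label)) scen$label <- cfg$label
  scen
}
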