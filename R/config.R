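#' Read pool and saturation parameters from a config file
#'
#' Accepts YAML (or JSON, a YAML subset) with optional top-level sections
#' `pools`, `cest_saturation` and `wassr_saturation`; fields within each
#' section override the package defaults ([pool_system()], [cest_scheme()],
#' [wassr_scheme()]).
#'
#' @param path Config file.
#' @return List with `pools`, `cest_sat`, `wassr_sat`.
#' @examples
#' cfg <- system.file("extdata", "example_config.yaml", package = "glucestr")
#' read_model_config(cfg)$pools
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  merge_into <- function(defaults, overrides, constructor) {
    if (!is.null(overrides)) {
      bad <- setdiff(names(overrides), names(defaults))
      if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      defaults[names(overrides)] <- overrides
    }
    do.call(constructor, defaults)
  }
  list(
    pools = merge_into(unclass(pool_system()), raw$pools, pool_system),
    cest_sat = merge_into(unclass(cest_scheme()), raw$cest_saturation,
                          saturation_scheme),
    wassr_sat = merge_into(unclass(wassr_scheme()), raw$wassr_saturation,
                           saturation_scheme)
  )
}
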