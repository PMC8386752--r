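# YAML configuration: `design:` mirrors design_params(), `hybridization:`
# mirrors hybridization_condition().

#' Read design configuration from YAML
#'
#' The file may contain a `design:` block (keys mirroring [design_params()])
#' and a `hybridization:` block (keys mirroring
#' [hybridization_condition()]); absent keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return List with elements `params` and `condition`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dp <- cfg$design %||% list()
  hy <- cfg$hybridization %||% list()
  allowed_dp <- names(formals(design_params))
  allowed_hy <- names(formals(hybridization_condition))
  bad <- c(setdiff(names(dp), allowed_dp), setdiff(names(hy), allowed_hy))
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(
    params = do.call(design_params, dp),
    condition = do.call(hybridization_condition, hy)
  )
}
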