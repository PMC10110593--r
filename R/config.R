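#' Read an analysis/simulation configuration file
#'
#' YAML configuration with optional blocks `reference` (FASTA path or
#' inline sequences), `model` (JSON path), `layout`, `calling`
#' (`min_reads`, `min_umis`), and `pgen_filter` (`threshold`). Unknown keys
#' are preserved.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Resolve reference and model objects from a configuration
#'
#' @param config List from [read_config()].
#' @return List with `reference` and `model` (falling back to the package
#'   defaults where unspecified).
#' @export
resolve_config <- function(config) {
  ref <- if (!is.null(config$reference)) {
    if (is.character(config$reference)) read_reference(config$reference)
    else do.call(cassette_reference, config$reference)
  } else default_reference()
  mod <- if (!is.null(config$model)) {
    if (is.character(config$model)) read_model(config$model)
    else default_model(ref)
  } else default_model(ref)
  list(reference = ref, model = mod)
}
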