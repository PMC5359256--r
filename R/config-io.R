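# Structured (YAML) configuration files for networks and simulations.

#' Write or read a network configuration file
#'
#' Flat key-value serialisation of a [network_config()] (plasticity-type
#' table and depression constants included) for scripted runs; the YAML
#' format keeps configurations diffable and hand-editable.
#'
#' @param config A [network_config()].
#' @param path File path.
#' @return `read_config()` returns a `stngpe_config`.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("the yaml package is required for config files")
  x <- unclass(config)
  x$stp_types <- as.data.frame(x$stp_types)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("the yaml package is required for config files")
  x <- yaml::read_yaml(path)
  x$stp_types <- as_tibble(as.data.frame(lapply(x$stp_types, unlist)))
  cfg <- do.call(network_config, x[names(x) %in% names(formals(network_config))])
  cfg
}
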