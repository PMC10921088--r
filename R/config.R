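# YAML configuration surface: each top-level section maps onto the matching
# constructor's arguments (phantom -> phantom_config, network ->
# network_config, train -> train_config, split -> split_spec, clahe ->
# clahe_params, augment -> augment_params).

.cfg_call <- function(fun, args) {
  if (is.null(args)) return(fun())
  keep <- intersect(names(args), names(formals(fun)))
  bad <- setdiff(names(args), names(formals(fun)))
  if (length(bad))
    warning("ignoring unknown config fields: ", paste(bad, collapse = ", "))
  do.call(fun, args[keep])
}

#' Read an experiment configuration from YAML
#'
#' Recognized sections: `phantom`, `network`, `train`, `split`, `clahe`,
#' `augment`, plus a top-level `skip_modes` character vector. Each section's
#' fields are the arguments of the matching constructor
#' ([phantom_config()], [network_config()], [train_config()],
#' [split_spec()], [clahe_params()], [augment_params()]); omitted sections
#' fall back to defaults (a missing/`null` `clahe` section disables
#' enhancement).
#'
#' @param path YAML file path.
#' @return a named list of constructed configuration objects.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list(
    phantom = .cfg_call(phantom_config, raw$phantom),
    network = .cfg_call(network_config, raw$network),
    train = .cfg_call(train_config, raw$train),
    split = .cfg_call(split_spec, raw$split),
    clahe = if (is.null(raw$clahe)) NULL else .cfg_call(clahe_params,
                                                        raw$clahe),
    augment = if (is.null(raw$augment)) NULL else .cfg_call(augment_params,
                                                            raw$augment),
    skip_modes = raw$skip_modes %||% c("watunet", "plain")
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
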