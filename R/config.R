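#' Load and validate a run configuration
#'
#' Reads a YAML document describing a run: a `preset` name plus optional
#' `n_replicates`, `seed`, and a `params` block of parameter overrides.
#' Unknown top-level keys and unknown parameter names are rejected with an
#' error naming the offending key; parameter values are validated by the
#' model's parameter constructor (range checks included).
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list of class `bh_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg A configuration list (as read from YAML).
#' @export
validate_config <- function(cfg) {
  allowed <- c("preset", "n_replicates", "seed", "params")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "))
  if (is.null(cfg$preset)) stop("configuration must name a 'preset'")
  if (!cfg$preset %in% preset_names())
    stop("unknown preset '", cfg$preset, "'; valid presets: ",
         paste(preset_names(), collapse = ", "))
  cfg$params <- as.list(cfg$params)
  if (length(cfg$params)) {
    known <- unique(c(names(formals(bee_params)), names(formals(fish_params)),
                      names(formals(plant_params))))
    bad <- setdiff(names(cfg$params), known)
    if (length(bad))
      stop("unknown parameter(s) in config: ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  ## materialise once so range violations surface at load time
  experiment_preset(cfg$preset, cfg$params)
  structure(cfg, class = "bh_config")
}

#' Save a run configuration
#'
#' Writes the configuration back to YAML; a saved and re-loaded configuration
#' validates to the same object.
#'
#' @param cfg A `bh_config` (or compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
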