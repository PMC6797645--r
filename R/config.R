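#' Pipeline configuration
#'
#' One object (and one YAML file) governs every pipeline command: export
#' dialect, interface geometry, exclusion policy, metric options, and the
#' simulator settings. Defaults reproduce the reference interface constants:
#' 700 ms latency alert threshold, 5000 ms answer limit, 6 practice and 10
#' recorded stimuli, 570 px button separation, 472 px button-to-Next
#' distance.
#'
#' @param dialect An [export_dialect()].
#' @param geom An [geometry()].
#' @param policy `"conservative"` or `"permissive"` exclusion policy.
#' @param options A [metric_options()].
#' @param sim An [sim_config()].
#' @param seed Integer seed used by commands that randomize.
#' @return An object of class `mt_config`.
#' @export
pipeline_config <- function(dialect = export_dialect(),
                            geom = geometry(),
                            policy = c("conservative", "permissive"),
                            options = metric_options(),
                            sim = sim_config(geometry = geom),
                            seed = 1L) {
  policy <- match.arg(policy)
  structure(list(dialect = dialect, geom = geom, policy = policy,
                 options = options, sim = sim, seed = as.integer(seed)),
            class = "mt_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config An [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mt_config"))
  sim <- unclass(config$sim)
  sim$geometry <- NULL  # geometry is stored once, at the top level
  lst <- list(
    dialect = list(separator = config$dialect$separator,
                   columns = as.list(config$dialect$columns),
                   n_trials = config$dialect$n_trials,
                   n_practice = config$dialect$n_practice,
                   skip_rows = config$dialect$skip_rows),
    geometry = unclass(config$geom),
    policy = config$policy,
    metrics = unclass(config$options),
    sim = sim,
    seed = config$seed
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Round trip holds: a config written by [write_config()] reads back
#' behavior-identical.
#'
#' @param path YAML path written by [write_config()] (or hand-edited).
#' @return An [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lst <- yaml::read_yaml(path)
  geom <- do.call(geometry, lst$geometry)
  dialect <- export_dialect(
    separator = lst$dialect$separator,
    columns = unlist(lst$dialect$columns),
    n_trials = lst$dialect$n_trials,
    n_practice = lst$dialect$n_practice,
    skip_rows = lst$dialect$skip_rows %||% 0)
  options <- do.call(metric_options, lst$metrics)
  sim_args <- lst$sim
  sim_args$geometry <- geom
  sim_args$zoom_factors <- unlist(sim_args$zoom_factors)
  sim <- do.call(sim_config, sim_args)
  pipeline_config(dialect = dialect, geom = geom, policy = lst$policy,
                  options = options, sim = sim, seed = lst$seed %||% 1L)
}

#' @export
print.mt_config <- function(x, ...) {
  cat("<mt_config> policy ", x$policy, ", seed ", x$seed, "\n", sep = "")
  print(x$dialect)
  print(x$geom)
  invisible(x)
}
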