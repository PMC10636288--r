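#' Assemble a run configuration
#'
#' Bundles everything a reproducible run needs: the hyperparameter
#' pool, the search configuration, the DEG thresholds, the fold count
#' and the master seed. The seed is stamped into every output.
#'
#' @param pool A [hyperparameter_pool()].
#' @param aco An [aco_config()].
#' @param fc_threshold,q_threshold DEG gate parameters (positive).
#' @param cv_folds Outer fold count (>= 2).
#' @param seed Integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(pool = default_pool(), aco = aco_config(),
                       fc_threshold = 1, q_threshold = 0.05,
                       cv_folds = 5L, seed = 1L) {
  if (fc_threshold <= 0 || q_threshold <= 0) stop("thresholds must be positive")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  structure(list(pool = pool, aco = aco,
                 deg = list(fc_threshold = as.numeric(fc_threshold),
                            q_threshold = as.numeric(q_threshold)),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "run_config")
}

# Internal: plain-list views for serialization
config_to_list <- function(cfg) {
  list(pool = unclass(cfg$pool), aco = unclass(cfg$aco), deg = cfg$deg,
       cv_folds = cfg$cv_folds, seed = cfg$seed)
}

config_from_list <- function(lst) {
  pool <- do.call(hyperparameter_pool,
                  lapply(lst$pool %||% list(), unlist))
  aco_args <- lst$aco %||% list()
  aco_args$seed <- aco_args$seed %||% lst$seed %||% 1L
  run_config(pool = pool, aco = do.call(aco_config, aco_args),
             fc_threshold = lst$deg$fc_threshold %||% 1,
             q_threshold = lst$deg$q_threshold %||% 0.05,
             cv_folds = lst$cv_folds %||% 5L, seed = lst$seed %||% 1L)
}

#' Read a run configuration from YAML or JSON
#'
#' File extension decides the parser (`.yaml`/`.yml` vs `.json`).
#' Omitted fields fall back to package defaults.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(lst)
}

#' Write a run configuration
#' @param cfg A [run_config()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  lst <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a machine-readable run report
#'
#' JSON containing the decoded best individual, the per-iteration best
#' fitness trace, the seed, and the full metrics; it round-trips
#' losslessly through [read_run_report()].
#'
#' @param result A `dnas_search_result` from [run_search()].
#' @param metrics A `metrics_report` from [classification_metrics()],
#'   or NULL.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(result, metrics, path) {
  stopifnot(inherits(result, "dnas_search_result"))
  report <- list(
    tool = "dnasearch",
    version = as.character(utils::packageVersion("dnasearch")),
    seed = result$seed,
    best_individual = unclass(result$best_individual),
    best_fitness = result$best_fitness,
    trace = result$trace,
    metrics = if (!is.null(metrics)) list(
      confusion = unname(apply(metrics$confusion, 1L, as.integer,
                               simplify = FALSE)),
      class_names = rownames(metrics$confusion),
      per_class = metrics$per_class,
      overall_accuracy = metrics$overall_accuracy,
      macro_accuracy = metrics$macro_accuracy,
      macro_sensitivity = metrics$macro_sensitivity,
      macro_specificity = metrics$macro_specificity,
      n = metrics$n))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' Read a run report written by [write_run_report()]
#' @param path Report path.
#' @return Nested list mirroring the written structure.
#' @export
read_run_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a run manifest
#'
#' Provenance stamp written before any other artifact: tool version,
#' seed, subcommand, input file checksums (md5) and ISO timestamp.
#'
#' @param dir Output directory.
#' @param subcommand CLI subcommand name.
#' @param seed Integer seed.
#' @param inputs Named character vector of input file paths.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, seed, inputs = character(0L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  existing <- inputs[file.exists(inputs)]
  manifest <- list(tool = "dnasearch",
                   version = as.character(utils::packageVersion("dnasearch")),
                   subcommand = subcommand, seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   inputs = as.list(tools::md5sum(existing)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
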