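## keys an experiment config may contain (all experiment_plan arguments)
.plan_keys <- c("scenario", "n_levels", "harvest_level", "f", "f_error_cv",
                "evolve", "tradeoffs", "burn_in", "harvest_iters",
                "replicates", "base_seed", "phase_scale", "pop_scale",
                "rate_scale", "resource", "founder", "mutation", "init_sizes")

#' Serialize an experiment plan to a plain list
#'
#' @param plan An [experiment_plan()].
#' @return A named list (suitable for [yaml::as.yaml()]); parsing it back
#'   with [config_to_plan()] reproduces the plan exactly.
#' @export
plan_to_config <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  out <- unclass(plan)
  out$tradeoffs <- lapply(plan$tradeoffs, as.list)
  out$evolve <- as.list(plan$evolve)      # survives yaml for length 0/1
  out$init_sizes <- as.list(plan$init_sizes)
  out
}

#' Build an experiment plan from a configuration list
#'
#' Validates key names and value ranges (via the [experiment_plan()]
#' constructor) and fills defaults; errors name the offending key.
#'
#' @param config Named list, e.g. parsed from a YAML file.
#' @return An `"experiment_plan"`.
#' @export
config_to_plan <- function(config) {
  if (is.null(names(config)) && length(config)) stop("config must be named")
  unknown <- setdiff(names(config), .plan_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  config$evolve <- as.integer(unlist(config$evolve))
  if (!is.null(config$init_sizes)) {
    config$init_sizes <- as.integer(unlist(config$init_sizes))
  }
  do.call(experiment_plan, config)
}

#' Load a configuration from a preset name or a YAML file
#'
#' @param x A scenario preset name (see [scenario_names()]) or the path of
#'   a YAML configuration file.
#' @param ... Overrides (passed to [scenario_preset()] for presets, merged
#'   over the file contents otherwise).
#' @return A fully resolved `"experiment_plan"`.
#' @export
load_config <- function(x, ...) {
  if (x %in% scenario_names()) return(scenario_preset(x, ...))
  if (!file.exists(x)) {
    stop("'", x, "' is neither a scenario preset nor an existing file; ",
         "presets: ", paste(scenario_names(), collapse = ", "))
  }
  cfg <- yaml::read_yaml(x)
  cfg <- utils::modifyList(cfg, list(...))
  config_to_plan(cfg)
}

#' Write a configuration file
#'
#' @param plan An [experiment_plan()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(plan, path) {
  writeLines(yaml::as.yaml(plan_to_config(plan)), path)
  invisible(path)
}

## fixed, documented column order for the record CSV
.record_cols <- c("iteration", "level", "abundance", "births", "deaths",
                  "n_eaten", "yield", "mean_G", "sd_G", "branch",
                  "replicate", "gen_sum", "gen_n", "resource")

#' Write experiment outputs to a directory
#'
#' Writes the per-iteration record CSV (fixed column order), the summary
#' CSV, the branch comparison CSV (for bifurcated runs), the resolved
#' configuration and a JSON manifest listing every file with its MD5 along
#' with the base seed and the configuration hash. Identical inputs produce
#' byte-identical files.
#'
#' @param runs A `"bifurcated_runs"` object, or a bare `"run_record"` data
#'   frame.
#' @param dir Output directory (created if missing).
#' @param plan The plan behind a bare record (taken from `runs` otherwise).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(runs, dir, plan = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(runs, "bifurcated_runs")) {
    records <- runs$records
    plan <- runs$plan
  } else {
    records <- runs
  }
  records <- .with_groups(as.data.frame(records))
  for (cn in setdiff(.record_cols, names(records))) records[[cn]] <- NA
  records <- records[, .record_cols]
  files <- character(0)

  rec_path <- file.path(dir, "records.csv")
  utils::write.csv(records, rec_path, row.names = FALSE)
  files <- c(files, "records.csv")

  if (nrow(records) > 0) {
    sum_path <- file.path(dir, "summary.csv")
    utils::write.csv(summarize_timeseries(records), sum_path,
                     row.names = FALSE)
    files <- c(files, "summary.csv")
  }
  if (inherits(runs, "bifurcated_runs") && length(runs$plan$evolve)) {
    cmp <- compare_models(runs)
    cmp_df <- data.frame(
      scenario = cmp$scenario, harvest_level = cmp$harvest_level,
      n_replicates = cmp$n_replicates,
      abundance_ecoevo = cmp$abundance[["ecoevo"]],
      abundance_ecoonly = cmp$abundance[["ecoonly"]],
      mean_diff_abundance = cmp$mean_diff_abundance,
      mean_diff_yield = cmp$mean_diff_yield,
      p_value = cmp$p_value, sign = cmp$sign,
      collapse_ecoevo = cmp$collapse_frac[["ecoevo"]],
      collapse_ecoonly = cmp$collapse_frac[["ecoonly"]])
    utils::write.csv(cmp_df, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
    files <- c(files, "comparison.csv")
  }
  config_hash <- NA_character_
  if (!is.null(plan)) {
    write_config(plan, file.path(dir, "config.yaml"))
    files <- c(files, "config.yaml")
    config_hash <- unname(tools::md5sum(file.path(dir, "config.yaml")))
  }
  manifest <- list(
    files = lapply(files, function(fn) {
      list(name = fn, md5 = unname(tools::md5sum(file.path(dir, fn))))
    }),
    base_seed = if (!is.null(plan)) plan$base_seed else NA,
    config_hash = config_hash
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
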