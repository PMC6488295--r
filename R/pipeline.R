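## Pipeline entry point tying the modules together. Each subcommand reads
## and writes the package's CSV/JSON contracts and drops a run manifest
## (configuration + seeds + versions) next to its outputs, so any run is
## reproducible from the manifest. A thin command-line wrapper lives at
## inst/cli/clampadapt.R.

write_manifest <- function(out_path, subcommand, cfg) {
  manifest <- list(subcommand = subcommand,
                   config = cfg[!vapply(cfg, is.function, logical(1))],
                   package_version = as.character(packageVersion("clampadapt")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json_record(manifest, paste0(out_path, ".manifest.json"),
                    overwrite = TRUE)
}

resolve_design <- function(cfg) {
  if (!is.null(cfg$design_file)) return(read_schedule(cfg$design_file))
  build_design(cfg$design %||% "exp1",
               outcome = cfg$outcome,
               clamp_angle = cfg$clamp_angle,
               seed = cfg$seed %||% 1L)
}

resolve_params <- function(cfg) {
  if (!is.null(cfg$params_file)) read_json_record(cfg$params_file)
  else cfg$params
}

#' Run one pipeline step
#'
#' Subcommands:
#' * `simulate`: noiseless model trajectory for a design -> trajectory CSV;
#' * `synth`: synthetic multi-participant dataset -> trials CSV + ground
#'   truth JSON;
#' * `preprocess`: trial CSV -> participant- and group-level cycle-series
#'   CSVs + metrics JSON;
#' * `fit`: trial CSV (optionally grouped) + model -> fit JSON;
#' * `compare`: trial CSV + model set -> ranking CSV (model, k, R2, AIC);
#' * `bootstrap`: trial CSV + model -> parameter-CI CSV;
#' * `stats`: two-group metric comparison -> permutation-test JSON.
#'
#' `cfg` is a named list; common fields are `input`, `out` (output stem or
#' file), `design`/`design_file`, `outcome`, `model`, `models`,
#' `params`/`params_file`, `seed`, `n_starts`, `n_boot`, `n_perm`,
#' `column_map`, `baseline_cycles`, `overwrite`. Outputs never overwrite
#' existing files unless `overwrite = TRUE`.
#'
#' @param subcommand one of `"simulate"`, `"synth"`, `"preprocess"`,
#'   `"fit"`, `"compare"`, `"bootstrap"`, `"stats"`.
#' @param cfg named list of options (see Details).
#' @return list of paths written, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "synth", "preprocess",
                                        "fit", "compare", "bootstrap",
                                        "stats"),
                         cfg = list()) {
  subcommand <- match.arg(subcommand)
  out <- cfg$out %||% stop_clamp("cfg$out is required", "invalid_config_error")
  ow <- isTRUE(cfg$overwrite)
  seed <- cfg$seed %||% 1L
  paths <- switch(subcommand,
    simulate = {
      design <- resolve_design(cfg)
      traj <- simulate_model_trajectory(cfg$model, resolve_params(cfg),
                                        design)
      write_trajectory(traj, out, overwrite = ow)
      out
    },
    synth = {
      design <- resolve_design(cfg)
      cfgs <- generator_config(design, cfg$model, resolve_params(cfg),
                               n_participants = cfg$n_participants %||% 16,
                               noise_sd = cfg$noise_sd %||% 3.5,
                               bias_sd = cfg$bias_sd %||% 2,
                               contamination = cfg$contamination %||% 0,
                               seed = seed)
      res <- generate_experiment(list(group1 = cfgs))
      truth_path <- paste0(sub("\\.csv$", "", out), "_truth.json")
      write_trials(res$trials, out, overwrite = ow)
      write_json_record(res$truth, truth_path, overwrite = ow)
      c(out, truth_path)
    },
    preprocess = {
      trials <- read_trials(cfg$input, cfg$column_map)
      pre <- preprocess_trials(trials,
                               baseline_cycles = cfg$baseline_cycles %||% 2:10)
      stem <- sub("\\.csv$", "", out)
      p1 <- paste0(stem, "_cycles.csv")
      p2 <- paste0(stem, "_group_cycles.csv")
      p3 <- paste0(stem, "_metrics.json")
      write_cycle_series(pre$cycles, p1, overwrite = ow)
      write_cycle_series(pre$group_cycles, p2, overwrite = ow)
      metrics <- c(summary_metrics(pre$group_cycles),
                   list(early_adaptation_rate =
                          early_adaptation_rate(pre$group_cycles),
                        outlier_fraction = pre$outlier_fraction))
      write_json_record(metrics, p3, overwrite = ow)
      c(p1, p2, p3)
    },
    fit = {
      prep <- pipeline_fit_inputs(cfg)
      fit <- fit_model(cfg$model, prep$schedules, prep$observed,
                       n_starts = cfg$n_starts %||% 10, seed = seed)
      write_json_record(fit_record(fit), out, overwrite = ow)
      out
    },
    compare = {
      prep <- pipeline_fit_inputs(cfg)
      models <- cfg$models %||% c("movement_reinforcement",
                                  "adaptation_modulation", "dual_error")
      tab <- compare_models(models, prep$schedules, prep$observed,
                            n_starts = cfg$n_starts %||% 10, seed = seed)
      check_overwrite(out, ow)
      write.csv(tab, out, row.names = FALSE)
      out
    },
    bootstrap = {
      prep <- pipeline_fit_inputs(cfg)
      boot <- bootstrap_parameter_ci(cfg$model, prep$schedules,
                                     prep$series,
                                     n_boot = cfg$n_boot %||% 1000,
                                     seed = seed,
                                     n_starts = cfg$n_starts %||% 10)
      check_overwrite(out, ow)
      write.csv(boot$ci, out, row.names = FALSE)
      out
    },
    stats = {
      groups <- cfg$groups %||%
        stop_clamp("cfg$groups (list of metric vectors) is required",
                   "invalid_config_error")
      pt <- permutation_test(groups,
                             statistic = cfg$statistic %||% "mean_difference",
                             n_perm = cfg$n_perm %||% 10000, seed = seed)
      es <- effect_sizes(groups)
      write_json_record(permtest_record(pt, es), out, overwrite = ow)
      out
    })
  write_manifest(paths[1], subcommand, cfg)
  invisible(paths)
}

# shared input preparation for fit / compare / bootstrap: trials CSV (with
# optional `group` column) -> per-group schedules, group-averaged clamp
# cycle means, and participant cycle matrices
pipeline_fit_inputs <- function(cfg) {
  trials <- read_trials(cfg$input, cfg$column_map)
  pre <- preprocess_trials(trials,
                           baseline_cycles = cfg$baseline_cycles %||% 2:10)
  grp_col <- if ("group" %in% names(trials)) {
    gm <- unique(trials[c("participant", "group")])
    setNames(gm$group, gm$participant)
  } else {
    setNames(rep("group1", length(unique(trials$participant))),
             unique(trials$participant))
  }
  cyc <- pre$cycles
  cyc$group <- grp_col[as.character(cyc$participant)]
  groups <- split(cyc, cyc$group)
  if (!is.null(cfg$designs)) {
    # per-group designs, aligned by group name; entries may be design ids
    schedules <- lapply(names(groups), function(g) {
      d <- cfg$designs[[g]]
      if (is.character(d)) build_design(d, seed = cfg$seed %||% 1L) else d
    })
    names(schedules) <- names(groups)
  } else {
    design <- resolve_design(cfg)
    schedules <- lapply(groups, function(g) design)
  }
  series <- lapply(groups, participant_cycle_matrix)
  observed <- lapply(series, function(m) colMeans(m, na.rm = TRUE))
  list(schedules = schedules, observed = observed, series = series)
}
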