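## Synthetic trial-data generator. Emulates the layout of the deposited
## per-trial source data: per-participant trial sequences following the
## experiment block structures, hand angle = generative-model mean +
## per-target baseline bias + i.i.d. Gaussian motor noise, counterbalanced
## clamp direction, optional outlier contamination, and RT/MT columns from
## log-normals so the kinematic summaries have something to chew on.

#' Configuration for the synthetic-data generator
#'
#' Defaults reflect the behavioral conditions the experiments report:
#' baseline hand-angle SD near 3.1-3.6 degrees (default noise 3.5), small
#' per-target biases (SD 2 degrees), counterbalanced clockwise /
#' counterclockwise clamps, reaction times around 375 ms and movement
#' times around 150 ms.
#'
#' @param design a schedule from [build_design()].
#' @param model generative model id, see [clamp_models()].
#' @param params named list of generative parameters for `model`.
#' @param n_participants participants in the group.
#' @param noise_sd trial-to-trial motor noise SD, degrees.
#' @param bias_sd SD of the per-participant, per-target baseline bias,
#'   degrees.
#' @param contamination fraction of trials replaced by gross outliers
#'   (uniform in 90-150 degrees); must be in `[0, 0.05]`.
#' @param counterbalance alternate CW/CCW clamp directions across
#'   participants?
#' @param seed RNG seed for the whole group.
#' @return a `generator_config` list.
#' @export
generator_config <- function(design, model, params, n_participants = 16,
                             noise_sd = 3.5, bias_sd = 2,
                             contamination = 0, counterbalance = TRUE,
                             seed = 1L) {
  check_number(noise_sd, "noise_sd", 0, Inf, open = FALSE,
               class = "invalid_config_error")
  check_number(bias_sd, "bias_sd", 0, Inf, open = FALSE,
               class = "invalid_config_error")
  check_number(contamination, "contamination", 0, 0.05, open = FALSE,
               class = "invalid_config_error")
  structure(list(design = design, model = model, params = as.list(params),
                 n_participants = n_participants, noise_sd = noise_sd,
                 bias_sd = bias_sd, contamination = contamination,
                 counterbalance = counterbalance, seed = seed),
            class = "generator_config")
}

simulate_model_trajectory <- function(model, params, sched) {
  p <- as.list(params)
  switch(model,
    motor_correction = simulate_motor_correction(p, sched),
    movement_reinforcement = simulate_movement_reinforcement(
      p[c("A", "U")], p[c("A_prime", "s")], sched),
    adaptation_modulation = simulate_adaptation_modulation(p, sched),
    dual_error = simulate_dual_error(p, sched),
    mr_am = simulate_hybrid("mr_am", p, sched),
    mr_de = simulate_hybrid("mr_de", p, sched),
    stop_clamp(sprintf("unknown model '%s'", model), "unknown_model_error"))
}

#' Generate one synthetic participant
#'
#' Hand angle per trial is the generative model's expected output plus the
#' participant's per-target bias plus Gaussian motor noise; participants
#' clamped counterclockwise have their angles sign-flipped at generation
#' so that [flip_ccw()] recovers the canonical frame exactly. Optional
#' contamination replaces a random subset of trials with angles drawn
#' uniformly from 90-150 degrees.
#'
#' @param cfg a [generator_config()].
#' @param id participant identifier.
#' @param clamp_dir `"CW"` or `"CCW"`.
#' @param seed RNG seed; `NULL` draws from the current RNG state (used by
#'   [generate_experiment()], which seeds once per group).
#' @return a trial table (one row per trial).
#' @export
generate_participant <- function(cfg, id = "s01", clamp_dir = "CW",
                                 seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(seed, {
    sched <- cfg$design
    traj <- simulate_model_trajectory(cfg$model, cfg$params, sched)
    targets <- sort(unique(sched$target_deg))
    bias <- setNames(rnorm(length(targets), 0, cfg$bias_sd), targets)
    n <- nrow(sched)
    hand <- traj$y + bias[as.character(sched$target_deg)] +
      rnorm(n, 0, cfg$noise_sd)
    if (cfg$contamination > 0) {
      bad <- runif(n) < cfg$contamination
      hand[bad] <- runif(sum(bad), 90, 150)
    }
    sign <- if (clamp_dir == "CCW") -1 else 1
    data.frame(participant = id,
               trial = sched$trial,
               cycle = sched$cycle,
               block_cycle = sched$block_cycle,
               phase = sched$phase,
               block = sched$block,
               target_deg = sched$target_deg,
               clamp_dir = clamp_dir,
               hand_angle = as.numeric(sign * hand),
               rt = rlnorm(n, log(375), 0.15),
               mt = rlnorm(n, log(150), 0.12))
  })
}

#' Generate a multi-group synthetic experiment
#'
#' One [generator_config()] per group; clamp directions are
#' counterbalanced within each group. The generative ground truth (model,
#' parameters, noise levels, seeds) is returned alongside the trials for
#' parameter-recovery tests.
#'
#' @param cfgs named list of `generator_config` objects (names become
#'   group labels), or a single config.
#' @return list with `trials` (all groups, with a `group` column) and
#'   `truth` (per-group generative record).
#' @export
generate_experiment <- function(cfgs) {
  if (inherits(cfgs, "generator_config")) cfgs <- list(group1 = cfgs)
  if (is.null(names(cfgs)) || any(names(cfgs) == "")) {
    names(cfgs) <- paste0("group", seq_along(cfgs))
  }
  out <- lapply(names(cfgs), function(gname) {
    cfg <- cfgs[[gname]]
    with_seed(cfg$seed, {
      dirs <- if (cfg$counterbalance) {
        rep(c("CW", "CCW"), length.out = cfg$n_participants)
      } else {
        rep("CW", cfg$n_participants)
      }
      tabs <- lapply(seq_len(cfg$n_participants), function(i) {
        tab <- generate_participant(
          cfg, id = sprintf("%s_s%02d", gname, i), clamp_dir = dirs[i],
          seed = NULL)
        tab
      })
      tab <- do.call(rbind, tabs)
      tab$group <- gname
      tab
    })
  })
  trials <- do.call(rbind, out)
  rownames(trials) <- NULL
  truth <- lapply(cfgs, function(cfg) {
    list(model = cfg$model, params = cfg$params, noise_sd = cfg$noise_sd,
         bias_sd = cfg$bias_sd, contamination = cfg$contamination,
         n_participants = cfg$n_participants, seed = cfg$seed)
  })
  list(trials = trials, truth = truth)
}
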