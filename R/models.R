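## Trial-by-trial learning models.
##
## Conventions shared by all simulators:
##  * hand angles are in degrees; positive = direction opposite the clamp;
##  * x(1) = 0 and all reinforcement weights start at 0 (baseline-corrected
##    data start at 0 by construction);
##  * the state used for trial n's output is the state after trial n-1's
##    update (update-after-movement indexing, x(n+1) = ...);
##  * the SPE error term is present only on clamp-block trials, where it is
##    a constant unit indicator with U absorbing the magnitude (the clamp
##    makes e constant, so U(e) collapses to one parameter);
##  * target error TE = 1 - hit on clamp trials and 0 elsewhere;
##  * no-feedback, veridical and zero-clamp trials evolve by retention only.

sched_signals <- function(sched) {
  check_columns(sched, c("block", "hit"), "schedule")
  err <- as.numeric(sched$block == "clamp")
  hit <- as.numeric(sched$hit == 1)
  list(err = err, te = err * (1 - hit), rew = hit, n = nrow(sched))
}

# Thin wrappers over the compiled recursions (src/cores.cpp).
# core_lin: state recursion x(n+1) = A*x(n) + input(n), x(1) = 0, returning
# the state at each trial. core_am: gain-modulated recursion. core_reinforce:
# population-vector reinforcement over 36,000 direction units (0.01 degree
# resolution) carried exactly through its x/y components, combined with an
# adaptation state x into motor output y = (1 - V_l)*x + V_l*V_d.
core_lin <- function(A, input) cpp_core_lin(A, as.numeric(input))

core_am <- function(A, U, gamma_A, gamma_u, err, hit) {
  cpp_core_am(A, U, gamma_A, gamma_u, as.numeric(err), as.numeric(hit))
}

core_reinforce <- function(x, rew, A_prime, s) {
  cpp_core_reinforce(as.numeric(x), as.numeric(rew), A_prime, s)
}

as_params <- function(params, constructor) {
  if (inherits(params, "clamp_params")) params
  else do.call(constructor, as.list(params))
}

make_trajectory <- function(sched, x, y, extra = NULL) {
  tr <- data.frame(trial = sched$trial, cycle = sched$cycle,
                   block = sched$block, x = x, y = y)
  if (!is.null(extra)) tr <- cbind(tr, as.data.frame(extra))
  class(tr) <- c("clamp_trajectory", "data.frame")
  tr
}

#' Simulate the motor-correction state-space model
#'
#' Single-rate state space: `x(n+1) = A x(n) + U` on clamp trials,
#' `x(n+1) = A x(n)` on trials without an error signal; motor output
#' `y = x`.
#'
#' @param params [state_space_params()] (or a named list with `A`, `U`).
#' @param sched a schedule from [build_design()].
#' @return a `clamp_trajectory` data frame with per-trial `x` and `y`.
#' @examples
#' d <- build_design("exp1", outcome = "miss")
#' tr <- simulate_motor_correction(state_space_params(0.98, 0.2), d)
#' @export
simulate_motor_correction <- function(params, sched) {
  p <- as_params(params, state_space_params)
  sig <- sched_signals(sched)
  x <- core_lin(p$A, p$U * sig$err)
  make_trajectory(sched, x, x)
}

#' Simulate the movement-reinforcement model
#'
#' Adaptation evolves by the motor-correction recursion, insensitive to
#' task outcome. In parallel, an operant reinforcement process maintains a
#' population vector `V` over 36,000 directionally tuned units (0.01
#' degree resolution): on each hit trial the weight of the unit matching
#' the produced movement direction is incremented by `s`, and all weights
#' decay by `A_prime` on every trial. Motor output is the weighted sum
#' `y(n) = (1 - V_l) x(n) + V_l V_d`, where `V_d` is the vector direction
#' and `V_l` its length, clipped to `[0, 1]`. When `V_l = 0` the output is
#' `y = x` (the reinforcement term has zero weight).
#'
#' @param ss [state_space_params()] for the adaptation process.
#' @param rp [reinforcement_params()] for the reinforcement process.
#' @inheritParams simulate_motor_correction
#' @return a `clamp_trajectory` with columns `x`, `y`, `V_l`, `V_d`
#'   (`V_d` is `NA` when the vector has zero length).
#' @export
simulate_movement_reinforcement <- function(ss, rp, sched) {
  ss <- as_params(ss, state_space_params)
  rp <- as_params(rp, reinforcement_params)
  sig <- sched_signals(sched)
  x <- core_lin(ss$A, ss$U * sig$err)
  out <- core_reinforce(x, sig$rew, rp$A_prime, rp$s)
  make_trajectory(sched, x, out$y, out[c("V_l", "V_d")])
}

#' Simulate the adaptation-modulation model
#'
#' Task outcome acts as a gain on adaptation: on hit trials
#' `x(n+1) = gamma_A A x(n) + gamma_u U`; on miss trials the plain
#' motor-correction recursion applies. `y = x`.
#'
#' @param params [modulation_params()].
#' @inheritParams simulate_motor_correction
#' @export
simulate_adaptation_modulation <- function(params, sched) {
  p <- as_params(params, modulation_params)
  sig <- sched_signals(sched)
  x <- core_am(p$A, p$U, p$gamma_A, p$gamma_u, sig$err, sig$rew)
  make_trajectory(sched, x, x)
}

#' Simulate the dual-error model
#'
#' Motor output is the sum of two independent state-space processes:
#' one driven by the (always present) sensory prediction error,
#' `x_spe(n+1) = A_spe x_spe(n) + U_spe` on clamp trials, and one driven
#' by the binary target error, `x_te(n+1) = A_te x_te(n) + U_te TE(n)`,
#' whose error term is present only on miss/straddle clamp trials.
#'
#' @param params [dual_error_params()].
#' @inheritParams simulate_motor_correction
#' @return a `clamp_trajectory` with `x` (= `x_spe + x_te`), `y`, and
#'   components `x_spe`, `x_te`.
#' @export
simulate_dual_error <- function(params, sched) {
  p <- as_params(params, dual_error_params)
  sig <- sched_signals(sched)
  x_spe <- core_lin(p$A_spe, p$U_spe * sig$err)
  x_te <- core_lin(p$A_te, p$U_te * sig$te)
  x <- x_spe + x_te
  make_trajectory(sched, x, x, list(x_spe = x_spe, x_te = x_te))
}

#' Simulate hybrid models
#'
#' Hybrids combine the movement-reinforcement machinery with either the
#' adaptation-modulation model (`"mr_am"`) or the dual-error model
#' (`"mr_de"`): the adaptation contribution `x` entering the output
#' equation `y = (1 - V_l) x + V_l V_d` is taken from the gain-modulated
#' recursion or from `x_total = x_spe + x_te`, respectively. Each hybrid
#' has six parameters. Setting `s` to its no-reinforcement limit recovers
#' the core model exactly; setting both gains to 1 in `"mr_am"` recovers
#' the movement-reinforcement model exactly.
#'
#' @param variant `"mr_am"` or `"mr_de"`.
#' @param params named list of the six parameters (`A`, `U`, `gamma_A`,
#'   `gamma_u`, `A_prime`, `s` for `"mr_am"`; `A_spe`, `U_spe`, `A_te`,
#'   `U_te`, `A_prime`, `s` for `"mr_de"`).
#' @inheritParams simulate_motor_correction
#' @export
simulate_hybrid <- function(variant = c("mr_am", "mr_de"), params, sched) {
  variant <- match.arg(variant)
  params <- as.list(params)
  rp <- reinforcement_params(params$A_prime, params$s)
  sig <- sched_signals(sched)
  extra <- NULL
  if (variant == "mr_am") {
    mp <- modulation_params(params$A, params$U, params$gamma_A,
                            params$gamma_u)
    x <- core_am(mp$A, mp$U, mp$gamma_A, mp$gamma_u, sig$err, sig$rew)
  } else {
    dp <- dual_error_params(params$A_spe, params$U_spe, params$A_te,
                            params$U_te)
    x_spe <- core_lin(dp$A_spe, dp$U_spe * sig$err)
    x_te <- core_lin(dp$A_te, dp$U_te * sig$te)
    x <- x_spe + x_te
    extra <- list(x_spe = x_spe, x_te = x_te)
  }
  out <- core_reinforce(x, sig$rew, rp$A_prime, rp$s)
  make_trajectory(sched, x, out$y, c(extra, out[c("V_l", "V_d")]))
}

#' Closed-form steady states under a constant outcome regime
#'
#' Fixed point of the relevant recursion under an unbroken sequence of
#' clamp trials with constant outcome. For the movement-reinforcement
#' model (and the hybrids, which embed it) the all-hit fixed point depends
#' on the reinforcement history and is not a schedule-free quantity;
#' requesting it raises an `unsupported_regime_error`. Under all-miss the
#' reinforcement weights decay to zero, so those models reduce to their
#' adaptation cores.
#'
#' @param model one of `"motor_correction"`, `"movement_reinforcement"`,
#'   `"adaptation_modulation"`, `"dual_error"`, `"mr_am"`, `"mr_de"`.
#' @param params named list of parameters for that model.
#' @param outcome_regime `"all_hit"` or `"all_miss"`.
#' @return asymptotic motor output, degrees.
#' @examples
#' steady_state("motor_correction", list(A = 0.9, U = 1), "all_miss")  # 10
#' @export
steady_state <- function(model, params,
                         outcome_regime = c("all_hit", "all_miss")) {
  outcome_regime <- match.arg(outcome_regime)
  p <- as.list(params)
  fp <- function(A, U) {
    if (A >= 1) stop_clamp("retention product must be < 1 for a fixed point",
                           "parameter_domain_error")
    U / (1 - A)
  }
  if (model %in% c("movement_reinforcement", "mr_am", "mr_de") &&
      outcome_regime == "all_hit") {
    stop_clamp(paste("the all-hit fixed point of the reinforcement process",
                     "depends on the schedule history"),
               "unsupported_regime_error")
  }
  switch(model,
    motor_correction = fp(p$A, p$U),
    movement_reinforcement = fp(p$A, p$U),
    adaptation_modulation = if (outcome_regime == "all_hit") {
      fp(p$gamma_A * p$A, p$gamma_u * p$U)
    } else {
      fp(p$A, p$U)
    },
    dual_error = if (outcome_regime == "all_hit") {
      fp(p$A_spe, p$U_spe)
    } else {
      fp(p$A_spe, p$U_spe) + fp(p$A_te, p$U_te)
    },
    mr_am = fp(p$A, p$U),
    mr_de = fp(p$A_spe, p$U_spe) + fp(p$A_te, p$U_te),
    stop_clamp(sprintf("unknown model '%s'", model), "unknown_model_error"))
}

#' Write a trajectory as CSV
#'
#' @param trajectory a `clamp_trajectory`.
#' @param path output file.
#' @param overwrite overwrite an existing file?
#' @export
write_trajectory <- function(trajectory, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
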