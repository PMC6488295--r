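## Model fitting: bounded multi-start least squares on clamp-phase cycle
## means, single group or several groups simultaneously with one shared
## parameter set; AIC / R-squared comparison; participant-resampling
## bootstrap confidence intervals.

.fit_eps <- 1e-6

#' Model registry for fitting
#'
#' Parameter names, bounds and simulator for each fittable model.
#' Bounds follow the fitting constraints `0 < A < 1` and `0 < U < e` for
#' every retention/update pair, `0 < A' < 1` and `0 < s < 1` for the
#' reinforcement process, and gains in `(0, 5]`.
#'
#' @param model model id: `"motor_correction"`, `"movement_reinforcement"`,
#'   `"adaptation_modulation"`, `"dual_error"`, `"mr_am"`, `"mr_de"`.
#' @param e clamp size in degrees (upper bound for update parameters).
#' @return list with `par_names`, `lower`, `upper`, `k`, `simulate`.
#' @keywords internal
model_info <- function(model, e) {
  b <- function(names, lower, upper) {
    list(par_names = names, lower = setNames(lower, names),
         upper = setNames(upper, names), k = length(names))
  }
  ret <- c(.fit_eps, 1 - .fit_eps)
  upd <- c(.fit_eps, e - .fit_eps)
  gain <- c(.fit_eps, 5)
  info <- switch(model,
    motor_correction = c(b(c("A", "U"), c(ret[1], upd[1]),
                           c(ret[2], upd[2])),
      list(simulate = function(p, sig) core_lin(p[["A"]],
                                                p[["U"]] * sig$err))),
    movement_reinforcement = c(b(c("A", "U", "A_prime", "s"),
                                 c(ret[1], upd[1], ret[1], .fit_eps),
                                 c(ret[2], upd[2], ret[2], 1 - .fit_eps)),
      list(simulate = function(p, sig) {
        x <- core_lin(p[["A"]], p[["U"]] * sig$err)
        core_reinforce(x, sig$rew, p[["A_prime"]], p[["s"]])$y
      })),
    adaptation_modulation = c(b(c("A", "U", "gamma_A", "gamma_u"),
                                c(ret[1], upd[1], gain[1], gain[1]),
                                c(ret[2], upd[2], gain[2], gain[2])),
      list(simulate = function(p, sig) {
        core_am(p[["A"]], p[["U"]], p[["gamma_A"]], p[["gamma_u"]],
                sig$err, sig$rew)
      })),
    dual_error = c(b(c("A_spe", "U_spe", "A_te", "U_te"),
                     c(ret[1], upd[1], ret[1], upd[1]),
                     c(ret[2], upd[2], ret[2], upd[2])),
      list(simulate = function(p, sig) {
        core_lin(p[["A_spe"]], p[["U_spe"]] * sig$err) +
          core_lin(p[["A_te"]], p[["U_te"]] * sig$te)
      })),
    mr_am = c(b(c("A", "U", "gamma_A", "gamma_u", "A_prime", "s"),
                c(ret[1], upd[1], gain[1], gain[1], ret[1], .fit_eps),
                c(ret[2], upd[2], gain[2], gain[2], ret[2], 1 - .fit_eps)),
      list(simulate = function(p, sig) {
        x <- core_am(p[["A"]], p[["U"]], p[["gamma_A"]], p[["gamma_u"]],
                     sig$err, sig$rew)
        core_reinforce(x, sig$rew, p[["A_prime"]], p[["s"]])$y
      })),
    mr_de = c(b(c("A_spe", "U_spe", "A_te", "U_te", "A_prime", "s"),
                c(ret[1], upd[1], ret[1], upd[1], ret[1], .fit_eps),
                c(ret[2], upd[2], ret[2], upd[2], ret[2], 1 - .fit_eps)),
      list(simulate = function(p, sig) {
        x <- core_lin(p[["A_spe"]], p[["U_spe"]] * sig$err) +
          core_lin(p[["A_te"]], p[["U_te"]] * sig$te)
        core_reinforce(x, sig$rew, p[["A_prime"]], p[["s"]])$y
      })),
    stop_clamp(sprintf("unknown model '%s'", model), "unknown_model_error"))
  info
}

#' Names of the fittable models
#' @return character vector of model ids.
#' @export
clamp_models <- function() {
  c("motor_correction", "movement_reinforcement", "adaptation_modulation",
    "dual_error", "mr_am", "mr_de")
}

as_group_list <- function(x) if (is.list(x) && !is.data.frame(x)) x else list(x)

# precompute the clamp-phase signals and trial->cycle mapping of a schedule
prepare_group <- function(sched) {
  cl <- sched[sched$block == "clamp", ]
  if (nrow(cl) == 0) {
    stop_clamp("schedule has no clamp trials to fit", "invalid_design_error")
  }
  cl <- cl[order(cl$trial), ]
  cyc <- match(cl$cycle, sort(unique(cl$cycle)))
  counts <- tabulate(cyc)
  # contiguous equal-sized cycles admit a reshape fast path for the means
  uniform <- length(unique(counts)) == 1L && !is.unsorted(cyc)
  list(sig = sched_signals(cl), cycle = cyc,
       counts = counts, n_cycles = max(cyc),
       uniform = uniform, per_cycle = counts[1],
       e = max(cl$clamp_deg))
}

sim_cycle_means <- function(info, par, grp) {
  y <- info$simulate(par, grp$sig)
  if (grp$uniform) {
    .colMeans(y, grp$per_cycle, grp$n_cycles)
  } else {
    as.numeric(rowsum(y, grp$cycle)) / grp$counts
  }
}

#' Least-squares loss of a model against observed cycle means
#'
#' Sum over groups and clamp cycles of squared differences between the
#' observed cycle means and the simulated cycle means (the mean of the
#' within-cycle trial outputs). Only clamp-block trials enter the loss.
#'
#' @param model model id, see [clamp_models()].
#' @param params named parameter vector (or `clamp_params` list).
#' @param schedules a schedule or list of schedules (one per group).
#' @param observed numeric vector of clamp-cycle means, or a list of such
#'   vectors aligned with `schedules`.
#' @param e clamp size; defaults to the largest clamp in the schedules.
#' @return SSE in degrees squared.
#' @export
loss_sse <- function(model, params, schedules, observed, e = NULL) {
  schedules <- as_group_list(schedules)
  observed <- if (is.list(observed)) observed else list(observed)
  groups <- lapply(schedules, prepare_group)
  e <- e %||% max(vapply(groups, `[[`, numeric(1), "e"))
  info <- model_info(model, e)
  par <- unlist(as.list(params))[info$par_names]
  if (anyNA(par)) {
    stop_clamp(sprintf("params must supply: %s",
                       paste(info$par_names, collapse = ", ")),
               "parameter_domain_error")
  }
  sum(vapply(seq_along(groups), function(g) {
    obs <- observed[[g]]
    if (length(obs) != groups[[g]]$n_cycles) {
      stop_clamp(sprintf(
        "group %d: %d observed cycle means but %d clamp cycles in schedule",
        g, length(obs), groups[[g]]$n_cycles), "misaligned_data_error")
    }
    sum((obs - sim_cycle_means(info, par, groups[[g]]))^2)
  }, numeric(1)))
}

aic_ls <- function(sse, n, k) n * log(max(sse, 1e-300) / n) + 2 * k

#' Fit a model to clamp-phase cycle means
#'
#' Bounded local optimization ([stats::nlminb()]) from `n_starts` random
#' interior start points drawn uniformly within the bounds under a fixed
#' seed; the best (lowest-SSE) start wins. When several groups are given
#' they are fit simultaneously with one shared parameter set (the sum of
#' per-group losses). Goodness of fit: `R2 = 1 - SSE/SST` with SST taken
#' about the mean of all observed cycle means pooled over groups, and the
#' least-squares Gaussian AIC `N log(SSE/N) + 2k` with `N` the number of
#' fitted cycle means and `k` the number of free parameters.
#'
#' @inheritParams loss_sse
#' @param n_starts number of random starts.
#' @param seed RNG seed for the start draws.
#' @param init optional extra start point(s): a named vector or a matrix
#'   with one row per start (used e.g. to warm-start bootstrap refits).
#' @return object of class `clampadapt_fit`: best `par`, `sse`,
#'   `r_squared`, `aic`, `n_obs`, `k`, per-start diagnostics in `starts`,
#'   and a `converged` flag.
#' @export
fit_model <- function(model, schedules, observed, e = NULL, n_starts = 10,
                      seed = 1L, init = NULL) {
  schedules <- as_group_list(schedules)
  observed <- if (is.list(observed)) observed else list(observed)
  stopifnot(length(schedules) == length(observed))
  groups <- lapply(schedules, prepare_group)
  e <- e %||% max(vapply(groups, `[[`, numeric(1), "e"))
  if (!is.finite(e) || e <= 0) {
    stop_clamp("clamp size 'e' must be positive for fitting",
               "invalid_design_error")
  }
  info <- model_info(model, e)
  for (g in seq_along(groups)) {
    if (length(observed[[g]]) != groups[[g]]$n_cycles) {
      stop_clamp(sprintf(
        "group %d: %d observed cycle means but %d clamp cycles in schedule",
        g, length(observed[[g]]), groups[[g]]$n_cycles),
        "misaligned_data_error")
    }
  }
  objective <- function(par) {
    total <- 0
    for (g in seq_along(groups)) {
      sim <- sim_cycle_means(info, par, groups[[g]])
      total <- total + sum((observed[[g]] - sim)^2)
    }
    # divergent corners of the box (e.g. gain * retention > 1) overflow the
    # state; a large finite loss keeps the optimizer on track
    if (!is.finite(total)) 1e300 else total
  }
  starts <- with_seed(seed, {
    matrix(runif(n_starts * info$k, info$lower, info$upper),
           nrow = n_starts, ncol = info$k, byrow = TRUE)
  })
  if (!is.null(init)) {
    init <- if (is.matrix(init)) init[, info$par_names, drop = FALSE]
            else matrix(unlist(init)[info$par_names], nrow = 1)
    init <- pmin(pmax(init, rep(info$lower, each = nrow(init))),
                 rep(info$upper, each = nrow(init)))
    starts <- rbind(init, starts)
  }
  n_starts <- nrow(starts)
  if (n_starts == 0) {
    stop_clamp("need at least one start point", "invalid_config_error")
  }
  colnames(starts) <- info$par_names
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tryCatch({
      opt <- nlminb(starts[i, ], objective, lower = info$lower,
                    upper = info$upper,
                    control = list(abs.tol = 1e-8, rel.tol = 1e-10,
                                   eval.max = 2000, iter.max = 500))
      list(par = opt$par, sse = opt$objective, code = opt$convergence,
           message = opt$message)
    }, error = function(err) {
      list(par = rep(NA_real_, info$k), sse = Inf, code = NA_integer_,
           message = conditionMessage(err))
    })
  }
  sses <- vapply(results, `[[`, numeric(1), "sse")
  ok <- is.finite(sses)
  if (!any(ok)) {
    stop_clamp(paste0("no start converged; messages: ",
                      paste(unique(vapply(results, `[[`, character(1),
                                          "message")), collapse = " | ")),
               "fit_failure_error")
  }
  best <- results[[which.min(sses)]]
  all_obs <- unlist(observed)
  n_obs <- length(all_obs)
  sst <- sum((all_obs - mean(all_obs))^2)
  start_df <- data.frame(start = seq_len(n_starts), starts,
                         sse = sses,
                         convergence = vapply(results, `[[`, numeric(1),
                                              "code"))
  structure(list(model = model,
                 par = setNames(as.numeric(best$par), info$par_names),
                 sse = best$sse,
                 r_squared = 1 - best$sse / sst,
                 aic = aic_ls(best$sse, n_obs, info$k),
                 n_obs = n_obs, k = info$k, e = e,
                 starts = start_df,
                 converged = any(start_df$convergence == 0, na.rm = TRUE)),
            class = "clampadapt_fit")
}

#' @export
print.clampadapt_fit <- function(x, ...) {
  cat(sprintf("Model fit: %s (k = %d, N = %d cycle means)\n",
              x$model, x$k, x$n_obs))
  print(round(x$par, 4))
  cat(sprintf("SSE = %.4g, R2 = %.4f, AIC = %.1f, converged: %s\n",
              x$sse, x$r_squared, x$aic, x$converged))
  invisible(x)
}

#' Fit and rank a set of models
#'
#' Fits each model to the same observations and tabulates the number of
#' free parameters, R-squared and AIC. Lower AIC ranks better; exact AIC
#' ties are broken in favor of fewer parameters.
#'
#' @inheritParams fit_model
#' @param models character vector of model ids.
#' @return data frame (model, k, sse, r_squared, aic) sorted best-first,
#'   with the individual fits in attribute `"fits"`.
#' @export
compare_models <- function(models, schedules, observed, e = NULL,
                           n_starts = 10, seed = 1L) {
  fits <- lapply(models, function(m)
    fit_model(m, schedules, observed, e = e, n_starts = n_starts,
              seed = seed))
  names(fits) <- models
  tab <- data.frame(model = models,
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    sse = vapply(fits, `[[`, numeric(1), "sse"),
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"))
  tab <- tab[order(tab$aic, tab$k), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Per-participant clamp-cycle matrix
#'
#' Reshapes a participant-level cycle series into a participants x
#' clamp-cycles matrix, the input the bootstrap resamples.
#'
#' @param cycles participant-level cycle series (see [aggregate_cycles()]).
#' @return numeric matrix, one row per participant, one column per clamp
#'   cycle (in cycle order).
#' @export
participant_cycle_matrix <- function(cycles) {
  cl <- cycles[cycles$block == "clamp", ]
  parts <- unique(cl$participant)
  cyc <- sort(unique(cl$cycle))
  m <- matrix(NA_real_, length(parts), length(cyc),
              dimnames = list(parts, cyc))
  m[cbind(match(cl$participant, parts), match(cl$cycle, cyc))] <-
    cl$hand_angle
  m
}

#' Bootstrap confidence intervals for model parameters
#'
#' Resamples participants with replacement within each group, rebuilds the
#' group-averaged clamp-cycle series, refits the model simultaneously to
#' all groups, and returns percentile confidence intervals of the fitted
#' parameters.
#'
#' @inheritParams fit_model
#' @param participant_series list (one per group) of participants x
#'   clamp-cycles matrices, see [participant_cycle_matrix()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param level confidence level.
#' @param boot_starts random starts per replicate refit. Replicates are
#'   additionally warm-started at the full-data solution (bootstrap
#'   samples perturb the data only mildly, so the full-data optimum is an
#'   excellent start); the full-data fit itself uses `n_starts` random
#'   starts.
#' @return object of class `clampadapt_boot`: `ci` (data frame parameter /
#'   lower / upper), the full-data `fit`, and the replicate draws in
#'   `replicates`.
#' @export
bootstrap_parameter_ci <- function(model, schedules, participant_series,
                                   n_boot = 1000, level = 0.95, seed = 1L,
                                   n_starts = 10, e = NULL,
                                   boot_starts = 1) {
  if (n_boot < 2) {
    stop_clamp("'n_boot' must be at least 2", "invalid_bootstrap_error")
  }
  schedules <- as_group_list(schedules)
  participant_series <- as_group_list(participant_series)
  stopifnot(length(schedules) == length(participant_series))
  full_obs <- lapply(participant_series,
                     function(m) colMeans(m, na.rm = TRUE))
  fit0 <- fit_model(model, schedules, full_obs, e = e, n_starts = n_starts,
                    seed = seed)
  draws <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      lapply(participant_series, function(m) {
        sample.int(nrow(m), nrow(m), replace = TRUE)
      })
    })
  })
  reps <- matrix(NA_real_, n_boot, fit0$k,
                 dimnames = list(NULL, names(fit0$par)))
  for (b in seq_len(n_boot)) {
    obs <- lapply(seq_along(participant_series), function(g) {
      colMeans(participant_series[[g]][draws[[b]][[g]], , drop = FALSE],
               na.rm = TRUE)
    })
    fit_b <- fit_model(model, schedules, obs, e = e, n_starts = boot_starts,
                       seed = seed + b, init = fit0$par)
    reps[b, ] <- fit_b$par
  }
  alpha <- (1 - level) / 2
  ci <- data.frame(parameter = colnames(reps),
                   estimate = as.numeric(fit0$par),
                   lower = apply(reps, 2, quantile, alpha),
                   upper = apply(reps, 2, quantile, 1 - alpha))
  rownames(ci) <- NULL
  structure(list(model = model, ci = ci, level = level, n_boot = n_boot,
                 fit = fit0, replicates = reps),
            class = "clampadapt_boot")
}

#' @export
print.clampadapt_boot <- function(x, ...) {
  cat(sprintf("Bootstrap parameter CIs: %s (%d replicates, %.0f%%)\n",
              x$model, x$n_boot, 100 * x$level))
  print(x$ci, digits = 4)
  invisible(x)
}
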