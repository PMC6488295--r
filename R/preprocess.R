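## Behavioral preprocessing: raw trial tables -> baseline-corrected cycle
## series and summary learning metrics. Canonical pipeline order is
## flip -> outlier screen -> baseline-bias subtraction -> cycle aggregation
## (flipping first pools clockwise and counterclockwise participants into
## one frame; the bias is computed on flipped, outlier-screened baseline
## trials).

.trial_cols <- c("participant", "trial", "cycle", "block", "target_deg",
                 "hand_angle")

#' Flip counterclockwise participants into the canonical frame
#'
#' Negates the hand angles of participants clamped in the counterclockwise
#' direction so all data share one sign convention (positive = opposite
#' the clamp). Apply exactly once: the operation is its own inverse, so a
#' second application undoes it.
#'
#' @param trials trial table with a `clamp_dir` column (`"CW"`/`"CCW"`).
#' @return the trial table with `hand_angle` flipped for CCW rows.
#' @export
flip_ccw <- function(trials) {
  check_columns(trials, c("clamp_dir", "hand_angle"))
  if (any(!trials$clamp_dir %in% c("CW", "CCW"))) {
    stop_clamp("'clamp_dir' must be \"CW\" or \"CCW\" on every trial",
               "invalid_direction_error")
  }
  ccw <- trials$clamp_dir == "CCW"
  trials$hand_angle[ccw] <- -trials$hand_angle[ccw]
  trials
}

# centered moving average with symmetric shrinking windows at the edges
# (window at i spans i-k..i+k with k = min((window-1)/2, i-1, n-i))
moving_average <- function(x, window = 5) {
  n <- length(x)
  i <- seq_len(n)
  k <- pmin((window - 1) %/% 2, i - 1L, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + k + 1L] - cs[i - k]) / (2 * k + 1)
}

#' Flag outlier trials
#'
#' Per participant and target location, computes a centered moving average
#' of hand angle (5-trial window, shrinking symmetrically at the edges)
#' and flags trials whose hand angle exceeds `abs_limit` in magnitude or
#' deviates from the moving average by more than `sd_mult` standard
#' deviations, where the SD is taken over that participant-and-target's
#' deviations from the moving average. Series shorter than the window
#' shrink to the series mean.
#'
#' @param trials trial table.
#' @param window moving-average window (trials).
#' @param abs_limit absolute hand-angle limit, degrees.
#' @param sd_mult multiple of the residual SD beyond which a trial is
#'   flagged.
#' @return logical vector, `TRUE` for trials to remove, aligned with the
#'   rows of `trials`.
#' @export
detect_outliers <- function(trials, window = 5, abs_limit = 90,
                            sd_mult = 3) {
  check_columns(trials, .trial_cols)
  mask <- logical(nrow(trials))
  groups <- split(seq_len(nrow(trials)),
                  list(trials$participant, trials$target_deg), drop = TRUE)
  for (idx in groups) {
    idx <- idx[order(trials$trial[idx])]
    ang <- trials$hand_angle[idx]
    resid <- ang - moving_average(ang, window)
    sd_r <- stats::sd(resid)
    flag <- abs(ang) > abs_limit
    if (is.finite(sd_r) && sd_r > 0) {
      flag <- flag | abs(resid) > sd_mult * sd_r
    }
    mask[idx] <- flag
  }
  mask
}

# derive the within-block cycle index when the table does not carry one
ensure_block_cycle <- function(trials) {
  if ("block_cycle" %in% names(trials)) return(trials)
  check_columns(trials, .trial_cols)
  trials$block_cycle <- NA_integer_
  for (idx in split(seq_len(nrow(trials)), trials$participant)) {
    idx <- idx[order(trials$trial[idx])]
    blk <- trials$block[idx]
    run <- cumsum(c(TRUE, blk[-1] != blk[-length(blk)]))
    cyc <- trials$cycle[idx]
    trials$block_cycle[idx] <- as.integer(
      stats::ave(cyc, run, FUN = function(x) x - min(x) + 1L))
  }
  trials
}

baseline_rows <- function(trials, baseline_cycles) {
  check_columns(trials, c(.trial_cols, "block_cycle"))
  trials$block == "baseline_veridical" &
    trials$block_cycle %in% baseline_cycles
}

#' Subtract per-target baseline biases
#'
#' For every participant and target location, subtracts the mean hand
#' angle over the stated cycles of the veridical-feedback baseline block
#' from all trials at that location. Cycles are counted within the block
#' (conventionally 2-10 for a 10-cycle baseline and 2-5 for a 5-cycle
#' one, dropping the first cycle).
#'
#' @param trials trial table (flipped and outlier-screened).
#' @param baseline_cycles within-block cycle numbers of the veridical
#'   baseline over which the bias is averaged.
#' @return the trial table with `hand_angle` bias-corrected; the biases are
#'   attached as attribute `"biases"` (participant x target data frame).
#' @export
subtract_baseline_bias <- function(trials, baseline_cycles = 2:10) {
  trials <- ensure_block_cycle(trials)
  bl <- trials[baseline_rows(trials, baseline_cycles), ]
  key <- function(p, t) paste(p, t, sep = "\r")
  need <- unique(key(trials$participant, trials$target_deg))
  have <- unique(key(bl$participant, bl$target_deg))
  if (length(setdiff(need, have))) {
    miss <- strsplit(setdiff(need, have)[1], "\r")[[1]]
    stop_clamp(sprintf(
      "no baseline trials for target %s deg (participant %s)",
      miss[2], miss[1]), "missing_baseline_error")
  }
  bias <- tapply(bl$hand_angle, key(bl$participant, bl$target_deg), mean)
  trials$hand_angle <- trials$hand_angle -
    as.numeric(bias[key(trials$participant, trials$target_deg)])
  biases <- do.call(rbind, lapply(names(bias), function(k) {
    parts <- strsplit(k, "\r")[[1]]
    data.frame(participant = parts[1], target_deg = as.numeric(parts[2]),
               bias = as.numeric(bias[k]))
  }))
  attr(trials, "biases") <- biases
  trials
}

#' Aggregate trials into cycle series
#'
#' A movement cycle is one reach to each target location; the cycle value
#' is the mean hand angle over the targets reached in that cycle. At the
#' group level the series is the mean over participants' per-cycle means.
#' Trials removed as outliers simply reduce the per-cycle trial count;
#' cycles with no surviving trials propagate as missing.
#'
#' @param trials trial table.
#' @param level `"participant"` (one series per participant) or `"group"`.
#' @return a cycle-series data frame with columns `participant` (if
#'   participant-level), `cycle`, `block_cycle`, `phase` (if present),
#'   `block`, `hand_angle`, `n`.
#' @export
aggregate_cycles <- function(trials, level = c("participant", "group")) {
  level <- match.arg(level)
  check_columns(trials, .trial_cols)
  keep <- c("block", intersect(c("block_cycle", "phase"), names(trials)))
  per_cycle <- function(df) {
    out <- aggregate(hand_angle ~ participant + cycle, data = df, mean)
    nn <- aggregate(hand_angle ~ participant + cycle, data = df, length)
    out$n <- nn$hand_angle
    meta <- df[!duplicated(df[c("participant", "cycle")]),
               c("participant", "cycle", keep)]
    out <- merge(out, meta, by = c("participant", "cycle"), sort = FALSE)
    out[order(out$participant, out$cycle),
        c("participant", "cycle", keep, "hand_angle", "n")]
  }
  cs <- per_cycle(trials)
  if (level == "group") {
    g <- aggregate(hand_angle ~ cycle, data = cs, mean)
    nn <- aggregate(hand_angle ~ cycle, data = cs, length)
    g$n <- nn$hand_angle
    meta <- cs[!duplicated(cs$cycle), c("cycle", keep)]
    g <- merge(g, meta, by = "cycle", sort = FALSE)
    cs <- g[order(g$cycle), c("cycle", keep, "hand_angle", "n")]
  }
  rownames(cs) <- NULL
  class(cs) <- c("cycle_series", "data.frame")
  cs
}

clamp_series <- function(cs) {
  cl <- cs[cs$block == "clamp", ]
  cl[order(cl$cycle), ]
}

#' Early adaptation rate
#'
#' Mean change in hand angle per cycle over the first five clamp cycles.
#' The default estimator averages clamp cycles 3-7 (a stabilized estimate
#' of the hand angle at cycle 5) and divides by five cycles from the zero
#' (baseline-corrected) start. `method = "slope"` instead returns the
#' regression slope of hand angle on cycle over clamp cycles 1-5.
#'
#' @param cs a cycle series (one participant or group mean).
#' @param method `"cycle5_mean"` (default) or `"slope"`.
#' @return degrees per cycle.
#' @export
early_adaptation_rate <- function(cs, method = c("cycle5_mean", "slope")) {
  method <- match.arg(method)
  cl <- clamp_series(cs)
  if (nrow(cl) < 7) {
    stop_clamp("need at least 7 clamp cycles for the early-rate metric",
               "insufficient_data_error")
  }
  if (method == "cycle5_mean") {
    mean(cl$hand_angle[3:7], na.rm = TRUE) / 5
  } else {
    unname(coef(lm(hand_angle ~ seq_along(hand_angle),
                   data = cl[1:5, ]))[2])
  }
}

#' Summary learning metrics for one cycle series
#'
#' * `late_learning`: mean hand angle over the last `last_n` clamp cycles;
#' * `aftereffect`: hand angle on the first cycle of the retention block
#'   (the block immediately following the last clamp cycle, a no-feedback
#'   or zero-clamp block);
#' * `retention_abs`: change from the final clamp cycle to the final
#'   retention-block cycle;
#' * `retention_ratio`: final retention-block cycle relative to the final
#'   clamp cycle.
#'
#' When the design has no retention block the retention metrics are `NA`
#' with `washout_available = FALSE` (never silently zero).
#'
#' @param cs a cycle series.
#' @param last_n number of final clamp cycles averaged for late learning.
#' @return named list of metrics.
#' @export
summary_metrics <- function(cs, last_n = 10) {
  cl <- clamp_series(cs)
  if (nrow(cl) == 0) {
    stop_clamp("cycle series contains no clamp cycles",
               "insufficient_data_error")
  }
  late <- mean(tail(cl$hand_angle, last_n), na.rm = TRUE)
  last_clamp_cycle <- max(cl$cycle)
  last_clamp <- cl$hand_angle[cl$cycle == last_clamp_cycle]
  post <- cs[cs$cycle > last_clamp_cycle, ]
  post <- post[post$block %in% c("washout_nofb", "zero_clamp"), ]
  if (nrow(post) == 0) {
    return(list(late_learning = late, aftereffect = NA_real_,
                retention_abs = NA_real_, retention_ratio = NA_real_,
                washout_available = FALSE))
  }
  wo_block <- post$block[which.min(post$cycle)]
  wo <- post[post$block == wo_block, ]
  wo <- wo[order(wo$cycle), ]
  last_wo <- tail(wo$hand_angle, 1)
  list(late_learning = late,
       aftereffect = wo$hand_angle[1],
       retention_abs = last_wo - last_clamp,
       retention_ratio = last_wo / last_clamp,
       washout_available = TRUE)
}

#' Late learning per clamp phase
#'
#' For transfer designs whose clamp block spans several phases, returns
#' the mean hand angle over the last `last_n` clamp cycles of each phase.
#'
#' @inheritParams summary_metrics
#' @return named numeric vector, one value per phase.
#' @export
late_learning_by_phase <- function(cs, last_n = 10) {
  check_columns(cs, "phase", "cycle series")
  cl <- clamp_series(cs)
  vapply(split(cl, cl$phase),
         function(df) mean(tail(df$hand_angle[order(df$cycle)], last_n),
                           na.rm = TRUE),
         numeric(1))
}

#' Baseline kinematics per participant
#'
#' Over the stated veridical-baseline cycles: hand-angle variability
#' (the SD of hand angles at each target location, averaged over
#' targets) and, when reaction/movement times are available, the average
#' over targets of the per-target median RT and MT.
#'
#' @param trials trial table (flipped; not bias-corrected - the SD is
#'   invariant to the per-target bias).
#' @param baseline_cycles within-block cycles of the veridical baseline.
#' @return data frame with one row per participant: `participant`,
#'   `hand_angle_sd`, `median_rt`, `median_mt`.
#' @export
baseline_kinematics <- function(trials, baseline_cycles = 2:10) {
  trials <- ensure_block_cycle(trials)
  bl <- trials[baseline_rows(trials, baseline_cycles), ]
  per_part <- split(bl, bl$participant)
  out <- lapply(names(per_part), function(p) {
    df <- per_part[[p]]
    by_t <- split(df, df$target_deg)
    sds <- vapply(by_t, function(d) stats::sd(d$hand_angle), numeric(1))
    med <- function(col) {
      if (!col %in% names(df)) return(NA_real_)
      mean(vapply(by_t, function(d) median(d[[col]], na.rm = TRUE),
                  numeric(1)))
    }
    data.frame(participant = p,
               hand_angle_sd = mean(sds),
               median_rt = med("rt"),
               median_mt = med("mt"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full preprocessing pipeline
#'
#' Flips counterclockwise participants, removes outlier trials, subtracts
#' per-target baseline biases, and aggregates to cycle series. The
#' pipeline is deterministic: rerunning on the same input yields identical
#' output.
#'
#' @param trials raw trial table.
#' @param baseline_cycles within-block baseline cycles for the bias (and
#'   kinematics).
#' @param window,abs_limit,sd_mult outlier-rule settings, see
#'   [detect_outliers()].
#' @return list with `trials` (clean, corrected), `cycles`
#'   (participant-level series), `group_cycles`, `outlier_fraction`,
#'   `biases`.
#' @export
preprocess_trials <- function(trials, baseline_cycles = 2:10, window = 5,
                              abs_limit = 90, sd_mult = 3) {
  trials <- ensure_block_cycle(flip_ccw(trials))
  mask <- detect_outliers(trials, window, abs_limit, sd_mult)
  clean <- trials[!mask, ]
  clean <- subtract_baseline_bias(clean, baseline_cycles)
  list(trials = clean,
       cycles = aggregate_cycles(clean, "participant"),
       group_cycles = aggregate_cycles(clean, "group"),
       outlier_fraction = mean(mask),
       biases = attr(clean, "biases"))
}
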