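#' Clamp-trial geometry
#'
#' Describes the endpoint geometry of one clamped-feedback condition: the
#' angular offset of the clamped cursor from the target and the physical
#' sizes of cursor and target on the (virtual) target ring.
#'
#' @param clamp_angle angular offset of the clamped cursor from the target
#'   center, degrees; must be in `[0, 90)`.
#' @param target_diameter target diameter, mm.
#' @param cursor_diameter feedback-cursor diameter, mm.
#' @param radial_distance radial distance from start to target ring, mm
#'   (default 80 mm, i.e. 8 cm).
#' @return an object of class `clamp_geometry`.
#' @examples
#' g <- clamp_geometry(3.5, 16, 3.5)
#' classify_task_outcome(g)
#' @export
clamp_geometry <- function(clamp_angle, target_diameter, cursor_diameter,
                           radial_distance = 80) {
  check_number(clamp_angle, "clamp_angle", lower = 0, upper = 90,
               open = FALSE, class = "invalid_geometry_error")
  if (clamp_angle >= 90) {
    stop_clamp("'clamp_angle' must be < 90 degrees", "invalid_geometry_error")
  }
  for (nm in c("target_diameter", "cursor_diameter", "radial_distance")) {
    check_number(get(nm), nm, lower = 0, upper = Inf, open = TRUE,
                 class = "invalid_geometry_error")
  }
  structure(list(clamp_angle = clamp_angle,
                 target_diameter = target_diameter,
                 cursor_diameter = cursor_diameter,
                 radial_distance = radial_distance),
            class = "clamp_geometry")
}

#' Classify the task outcome of a clamp geometry
#'
#' Computes the Euclidean center-to-center distance between the clamped
#' cursor endpoint and the target (the chord subtended by the clamp angle
#' on the target ring) and classifies the outcome: `hit` when the cursor
#' is fully embedded in the target, `miss` when it is fully outside, and
#' `straddle` otherwise. Boundary contact (cursor edge exactly on the
#' target edge) counts toward the embedded side, making the partition
#' closed and deterministic.
#'
#' @param g a [clamp_geometry()] object.
#' @return list with `outcome` (`"hit"`, `"straddle"` or `"miss"`) and
#'   `center_distance` (mm).
#' @examples
#' classify_task_outcome(clamp_geometry(3.5, 16, 3.5))   # hit, 4.9 mm
#' classify_task_outcome(clamp_geometry(3.5, 6, 3.5))    # miss
#' classify_task_outcome(clamp_geometry(1.75, 6, 3.5))   # straddle, 2.4 mm
#' @export
classify_task_outcome <- function(g) {
  stopifnot(inherits(g, "clamp_geometry"))
  d <- chord_distance(g$clamp_angle, g$radial_distance)
  r_target <- g$target_diameter / 2
  r_cursor <- g$cursor_diameter / 2
  outcome <- if (d + r_cursor <= r_target) {
    "hit"
  } else if (d - r_cursor >= r_target) {
    "miss"
  } else {
    "straddle"
  }
  list(outcome = outcome, center_distance = d)
}

# chord length between two points on a circle of radius R separated by
# `angle` degrees
chord_distance <- function(angle, radius) {
  2 * radius * sin(angle * pi / 360)
}

#' Largest target fully missed by a clamped cursor
#'
#' The maximal target diameter for which the clamped cursor lands fully
#' outside the target (boundary contact included), useful for checking
#' whether a full-miss condition is physically practical.
#'
#' @inheritParams clamp_geometry
#' @return target diameter in mm (can be negative when no full miss is
#'   geometrically possible).
#' @export
max_miss_target_diameter <- function(clamp_angle, cursor_diameter,
                                     radial_distance = 80) {
  2 * (chord_distance(clamp_angle, radial_distance) - cursor_diameter / 2)
}

.block_levels <- c("baseline_nofb", "baseline_veridical", "clamp",
                   "zero_clamp", "washout_nofb", "washout_veridical")

#' Build a per-trial clamp schedule
#'
#' Encodes the block structure of the clamp experiments as one row per
#' trial. Standard designs: `exp1` (3.5 deg clamp, 8 targets, 5 no-feedback
#' + 10 veridical baseline cycles, 80 clamp cycles, 5 no-feedback + 10
#' veridical washout cycles), `exp2` (1.75 deg clamp, 4 targets, 10 + 10
#' baseline, 220 clamp, 10 zero-clamp + 10 veridical washout),
#' `exp3_straddle_to_hit` / `exp3_hit_to_straddle` (1.75 deg clamp, 8
#' targets, 5 + 5 baseline, 120-cycle acquisition phase then 80-cycle
#' transfer phase with the task outcome reversed), and `exp3_control`
#' (hit outcome in both phases). Practice/instruction trials are excluded.
#'
#' The `hit` flag marks trials on which the cursor lands fully inside the
#' target: the scheduled outcome on clamp trials, 1 on zero-clamp trials
#' (a 0 deg clamp is centered in the target), and 0 on no-feedback and
#' veridical blocks (no scheduled reinforcement). Target order within each
#' cycle is a seeded random permutation; all analyses aggregate by cycle.
#'
#' @param experiment one of `"exp1"`, `"exp2"`, `"exp3_straddle_to_hit"`,
#'   `"exp3_hit_to_straddle"`, `"exp3_control"`; ignored when `phases` is
#'   supplied.
#' @param outcome task outcome during the clamp block for `exp1`/`exp2`
#'   (`"hit"`, `"straddle"` or `"miss"`); defaults to `"miss"` for `exp1`
#'   and `"straddle"` for `exp2`. `straddle` and `miss` are equivalent for
#'   the models (target error = 1 on both).
#' @param phases optional custom design: a list of phases, each a list
#'   with `n_cycles`, `block`, `e` (clamp size, degrees) and `hit` (0/1).
#' @param n_targets number of target locations per cycle (8 unless `exp2`).
#' @param clamp_angle clamp size in degrees for standard designs.
#' @param seed seed for the within-cycle target permutation.
#' @return a `data.frame` with columns `trial`, `cycle`, `block_cycle`,
#'   `phase`, `block`, `target_deg`, `clamp_deg`, `hit`.
#' @examples
#' d <- build_design("exp1", outcome = "hit")
#' sum(d$block == "clamp")  # 640 clamp trials
#' @export
build_design <- function(experiment = c("exp1", "exp2",
                                        "exp3_straddle_to_hit",
                                        "exp3_hit_to_straddle",
                                        "exp3_control"),
                         outcome = NULL, phases = NULL, n_targets = NULL,
                         clamp_angle = NULL, seed = 1L) {
  if (is.null(phases)) {
    experiment <- match.arg(experiment)
    std <- standard_phases(experiment, outcome, clamp_angle)
    phases <- std$phases
    n_targets <- n_targets %||% std$n_targets
  } else {
    n_targets <- n_targets %||% 8L
  }
  targets <- if (n_targets == 4L) c(45, 135, 225, 315) else
    seq(0, 360 - 360 / n_targets, by = 360 / n_targets)

  rows <- lapply(seq_along(phases), function(i) {
    ph <- phases[[i]]
    for (f in c("n_cycles", "block", "e", "hit")) {
      if (is.null(ph[[f]])) {
        stop_clamp(sprintf("phase %d is missing field '%s'", i, f),
                   "invalid_design_error")
      }
    }
    if (!ph$block %in% .block_levels) {
      stop_clamp(sprintf("phase %d: unknown block label '%s'", i, ph$block),
                 "invalid_design_error")
    }
    if (ph$n_cycles < 0 || ph$n_cycles != round(ph$n_cycles)) {
      stop_clamp(sprintf("phase %d: 'n_cycles' must be a non-negative integer",
                         i), "invalid_design_error")
    }
    if (ph$n_cycles == 0) return(NULL)
    data.frame(phase = i, block = ph$block, block_cycle_local =
                 rep(seq_len(ph$n_cycles), each = n_targets),
               clamp_deg = ph$e, hit = ph$hit)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    stop_clamp("design has no trials", "invalid_design_error")
  }
  n_cycles_total <- nrow(rows) / n_targets
  sched <- with_seed(seed, {
    target_deg <- as.vector(vapply(seq_len(n_cycles_total),
                                   function(i) sample(targets),
                                   numeric(n_targets)))
    cycle <- rep(seq_len(n_cycles_total), each = n_targets)
    # within-block cycle index restarts at each run of a block label
    run_id <- cumsum(c(TRUE, rows$block[-1] != rows$block[-nrow(rows)]))
    block_cycle <- stats::ave(cycle, run_id,
                              FUN = function(x) x - min(x) + 1L)
    data.frame(trial = seq_len(nrow(rows)),
               cycle = cycle,
               block_cycle = block_cycle,
               phase = rows$phase,
               block = rows$block,
               target_deg = target_deg,
               clamp_deg = rows$clamp_deg,
               hit = rows$hit)
  })
  class(sched) <- c("clamp_schedule", "data.frame")
  sched
}

standard_phases <- function(experiment, outcome, clamp_angle) {
  hit_flag <- function(outc) as.integer(identical(outc, "hit"))
  if (experiment == "exp1") {
    e <- clamp_angle %||% 3.5
    h <- hit_flag(match.arg(outcome %||% "miss", c("hit", "straddle", "miss")))
    list(n_targets = 8L, phases = list(
      list(n_cycles = 5, block = "baseline_nofb", e = 0, hit = 0),
      list(n_cycles = 10, block = "baseline_veridical", e = 0, hit = 0),
      list(n_cycles = 80, block = "clamp", e = e, hit = h),
      list(n_cycles = 5, block = "washout_nofb", e = 0, hit = 0),
      list(n_cycles = 10, block = "washout_veridical", e = 0, hit = 0)))
  } else if (experiment == "exp2") {
    e <- clamp_angle %||% 1.75
    h <- hit_flag(match.arg(outcome %||% "straddle", c("hit", "straddle")))
    list(n_targets = 4L, phases = list(
      list(n_cycles = 10, block = "baseline_nofb", e = 0, hit = 0),
      list(n_cycles = 10, block = "baseline_veridical", e = 0, hit = 0),
      list(n_cycles = 220, block = "clamp", e = e, hit = h),
      list(n_cycles = 10, block = "zero_clamp", e = 0, hit = 1),
      list(n_cycles = 10, block = "washout_veridical", e = 0, hit = 0)))
  } else {
    e <- clamp_angle %||% 1.75
    outcomes <- switch(experiment,
      exp3_straddle_to_hit = c(0L, 1L),
      exp3_hit_to_straddle = c(1L, 0L),
      exp3_control = c(1L, 1L))
    list(n_targets = 8L, phases = list(
      list(n_cycles = 5, block = "baseline_nofb", e = 0, hit = 0),
      list(n_cycles = 5, block = "baseline_veridical", e = 0, hit = 0),
      list(n_cycles = 120, block = "clamp", e = e, hit = outcomes[1]),
      list(n_cycles = 80, block = "clamp", e = e, hit = outcomes[2])))
  }
}

#' Write / read a schedule as CSV
#'
#' @param sched a schedule from [build_design()].
#' @param path output file.
#' @param overwrite overwrite an existing file?
#' @return `path`, invisibly (writer); the schedule (reader).
#' @export
write_schedule <- function(sched, path, overwrite = FALSE) {
  check_overwrite(path, overwrite)
  write.csv(as.data.frame(sched), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    stop_clamp(sprintf("schedule file not found: %s", path),
               "missing_file_error")
  }
  sched <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(sched, c("trial", "cycle", "block", "target_deg",
                         "clamp_deg", "hit"), "schedule CSV")
  class(sched) <- c("clamp_schedule", "data.frame")
  sched
}
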