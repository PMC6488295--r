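# small hand-built trial tables for the preprocessing rules

tiny_trials <- function(hand, participant = "p1", target = 0,
                        block = "clamp", clamp_dir = "CW") {
  n <- length(hand)
  data.frame(participant = participant, trial = seq_len(n),
             cycle = seq_len(n), block = block, target_deg = target,
             clamp_dir = clamp_dir, hand_angle = hand)
}

test_that("flip_ccw negates only counterclockwise participants", {
  tab <- rbind(tiny_trials(c(-12, 7), participant = "ccw",
                           clamp_dir = "CCW"),
               tiny_trials(c(7, -3), participant = "cw", clamp_dir = "CW"))
  out <- flip_ccw(tab)
  expect_equal(out$hand_angle[out$participant == "ccw"], c(12, -7))
  expect_equal(out$hand_angle[out$participant == "cw"], c(7, -3))
  expect_error(flip_ccw(transform(tab, clamp_dir = "sideways")),
               class = "invalid_direction_error")
  expect_error(flip_ccw(tab[, setdiff(names(tab), "clamp_dir")]),
               class = "missing_column_error")
})

test_that("moving average uses centered shrinking windows", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  # oracle: symmetric window, k = min(2, i-1, n-i)
  want <- vapply(seq_along(x), function(i) {
    k <- min(2, i - 1, length(x) - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
  expect_equal(clampadapt:::moving_average(x, 5), want)
  expect_equal(clampadapt:::moving_average(c(4, 8), 5), c(4, 8))
})

test_that("outlier rule flags absolute and moving-average violations", {
  # constant series: nothing flagged
  expect_false(any(detect_outliers(tiny_trials(rep(2, 12)))))

  # absolute rule is unconditional
  tab <- tiny_trials(c(rep(0, 6), 95, rep(0, 5)))
  expect_true(detect_outliers(tab)[7])

  # 3-SD rule: spike of 20 in a near-flat series; hand oracle for the
  # residual SD (four residuals of -4, one of 16, rest 0 -> sd = 4)
  x <- c(rep(0, 9), 20, rep(0, 11))
  ma <- vapply(seq_along(x), function(i) {
    k <- min(2, i - 1, length(x) - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
  resid <- x - ma
  expect_equal(sd(resid), 4)
  flags <- detect_outliers(tiny_trials(x))
  expect_identical(which(flags), 10L)

  # random series: flags agree with a literal oracle of the rule
  set.seed(1)
  noisy <- tiny_trials(rnorm(60, 0, 8))
  ang <- noisy$hand_angle
  ma2 <- vapply(seq_along(ang), function(i) {
    k <- min(2, i - 1, length(ang) - i)
    mean(ang[(i - k):(i + k)])
  }, numeric(1))
  res <- ang - ma2
  want <- abs(ang) > 90 | abs(res) > 3 * sd(res)
  expect_identical(detect_outliers(noisy), want)
})

test_that("outlier screening is per participant and target", {
  a <- tiny_trials(c(rep(0, 9), 20, rep(0, 11)), participant = "a")
  b <- tiny_trials(rnorm(21, 0, 10), participant = "b")
  set.seed(2)
  tab <- rbind(a, b)
  flags <- detect_outliers(tab)
  expect_true(flags[10])          # a's spike
  expect_false(any(flags[1:9]))   # a's flat stretch untouched
})

baseline_fixture <- function() {
  # 2 targets x 6 baseline cycles + 4 clamp cycles, biases +2 / -2
  bl <- expand.grid(cycle = 1:6, target_deg = c(0, 180))
  bl$block <- "baseline_veridical"
  bl$hand_angle <- ifelse(bl$target_deg == 0, 2, -2)
  cl <- expand.grid(cycle = 7:10, target_deg = c(0, 180))
  cl$block <- "clamp"
  cl$hand_angle <- 5 + ifelse(cl$target_deg == 0, 2, -2)
  tab <- rbind(bl, cl)
  tab <- tab[order(tab$cycle, tab$target_deg), ]
  tab$participant <- "p1"
  tab$trial <- seq_len(nrow(tab))
  tab$clamp_dir <- "CW"
  tab
}

test_that("baseline bias is subtracted per target, not globally", {
  tab <- baseline_fixture()
  out <- subtract_baseline_bias(tab, baseline_cycles = 2:6)
  expect_equal(unique(out$hand_angle[out$block == "clamp"]), 5)
  expect_equal(unique(out$hand_angle[out$block == "baseline_veridical"]), 0)
  biases <- attr(out, "biases")
  expect_equal(biases$bias[order(biases$target_deg)], c(2, -2))

  # zero-bias data unchanged
  zb <- tab
  zb$hand_angle <- 1
  out2 <- subtract_baseline_bias(zb, baseline_cycles = 2:6)
  expect_equal(unique(out2$hand_angle), 0)

  # missing baseline for a target is an error naming the target
  nobl <- tab[!(tab$block == "baseline_veridical" & tab$target_deg == 180), ]
  expect_error(subtract_baseline_bias(nobl, baseline_cycles = 2:6),
               "180", class = "missing_baseline_error")
})

test_that("cycle aggregation averages targets, participants, skips masks", {
  one_cycle <- data.frame(participant = "p1", trial = 1:8, cycle = 1,
                          block = "clamp",
                          target_deg = seq(0, 315, by = 45),
                          clamp_dir = "CW", hand_angle = 1:8)
  cs <- aggregate_cycles(one_cycle)
  expect_equal(cs$hand_angle, 4.5)
  expect_equal(cs$n, 8)

  # one masked (removed) trial: mean of the remaining 7
  cs7 <- aggregate_cycles(one_cycle[-1, ])
  expect_equal(cs7$hand_angle, mean(2:8))
  expect_equal(cs7$n, 7)

  # group series = mean over participants' cycle means
  two <- rbind(one_cycle,
               transform(one_cycle, participant = "p2",
                         hand_angle = hand_angle + 10))
  g <- aggregate_cycles(two, level = "group")
  expect_equal(g$hand_angle, mean(c(4.5, 14.5)))
  expect_equal(g$n, 2)
})

cs_from <- function(values, block = "clamp", start_cycle = 1) {
  structure(data.frame(cycle = start_cycle + seq_along(values) - 1,
                       block = block, hand_angle = values,
                       n = 8),
            class = c("cycle_series", "data.frame"))
}

test_that("early adaptation rate follows the cycles 3-7 definition", {
  expect_equal(early_adaptation_rate(cs_from(c(0, 0, rep(5, 5), 9, 9))), 1)
  expect_equal(early_adaptation_rate(cs_from(rep(0, 12))), 0)
  # linear ramp of 1 deg/cycle: mean of cycles 3-7 is 5
  expect_equal(early_adaptation_rate(cs_from(1:12)), 1)
  # slope variant on the first five cycles
  expect_equal(early_adaptation_rate(cs_from(1:12), method = "slope"), 1)
  expect_error(early_adaptation_rate(cs_from(1:3)),
               class = "insufficient_data_error")
})

test_that("summary metrics cover late learning, aftereffect, retention", {
  cs <- rbind(cs_from(c(rep(10, 10), rep(18, 10))),
              cs_from(c(20, 17, 15), block = "washout_nofb",
                      start_cycle = 21))
  m <- summary_metrics(cs)
  expect_equal(m$late_learning, 18)
  expect_equal(m$aftereffect, 20)
  expect_equal(m$retention_abs, 15 - 18)
  expect_equal(m$retention_ratio, 15 / 18)
  expect_true(m$washout_available)

  # no decay in washout: ratio 1
  cs2 <- rbind(cs_from(rep(18, 15)),
               cs_from(rep(18, 5), block = "washout_nofb",
                       start_cycle = 16))
  expect_equal(summary_metrics(cs2)$retention_ratio, 1)

  # no washout block: flagged unavailable, not zero
  m3 <- summary_metrics(cs_from(rep(18, 15)))
  expect_false(m3$washout_available)
  expect_true(is.na(m3$retention_ratio))
})

test_that("baseline kinematics: SD and medians averaged over targets", {
  base <- expand.grid(cycle = 1:11, target_deg = c(0, 180))
  base$block <- "baseline_veridical"
  base$participant <- "p1"
  base <- base[order(base$cycle), ]
  base$trial <- seq_len(nrow(base))
  base$clamp_dir <- "CW"
  # target 0: sd 2 pattern; target 180: sd 4 pattern over cycles 2-11
  set.seed(3)
  base$hand_angle <- 0
  base$hand_angle[base$target_deg == 0] <- scale(rnorm(11)) * 2
  base$hand_angle[base$target_deg == 180] <- scale(rnorm(11)) * 4
  base$rt <- ifelse(base$target_deg == 0, 300, 400)
  base$mt <- 150
  k <- baseline_kinematics(base, baseline_cycles = 1:11)
  expect_equal(k$hand_angle_sd, 3)          # mean of SDs 2 and 4
  expect_equal(k$median_rt, 350)
  expect_equal(k$median_mt, 150)

  # identical reaches: variability 0
  same <- transform(base, hand_angle = 5)
  expect_equal(baseline_kinematics(same, 1:11)$hand_angle_sd, 0)
})

test_that("pipeline is deterministic and converges to the model as noise -> 0", {
  des <- build_design(phases = list(
    list(n_cycles = 2, block = "baseline_nofb", e = 0, hit = 0),
    list(n_cycles = 6, block = "baseline_veridical", e = 0, hit = 0),
    list(n_cycles = 30, block = "clamp", e = 1.75, hit = 0)),
    n_targets = 4, seed = 4)
  cfg <- generator_config(des, "motor_correction", list(A = 0.9, U = 0.5),
                          n_participants = 4, noise_sd = 1e-9,
                          bias_sd = 1.5, seed = 9)
  trials <- generate_experiment(cfg)$trials
  # sd_mult is opened up: at noise ~ 0 the 3-SD rule measures the learning
  # curve's own curvature, which is not what this convergence check probes
  p1 <- preprocess_trials(trials, baseline_cycles = 2:6, sd_mult = 50)
  p2 <- preprocess_trials(trials, baseline_cycles = 2:6, sd_mult = 50)
  expect_identical(p1$group_cycles, p2$group_cycles)

  traj <- simulate_motor_correction(list(A = 0.9, U = 0.5), des)
  model_cycles <- tapply(traj$y[des$block == "clamp"],
                         des$cycle[des$block == "clamp"], mean)
  got <- p1$group_cycles$hand_angle[p1$group_cycles$block == "clamp"]
  expect_equal(got, as.numeric(model_cycles), tolerance = 1e-6)
})

test_that("outlier removal stays rare on clean data at realistic noise", {
  des <- build_design("exp1", outcome = "miss", seed = 6)
  cfg <- generator_config(des, "motor_correction", list(A = 0.98, U = 0.4),
                          n_participants = 6, noise_sd = 3.5, seed = 13)
  trials <- generate_experiment(cfg)$trials
  pre <- preprocess_trials(trials, baseline_cycles = 2:10)
  expect_lt(pre$outlier_fraction, 0.02)
})
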