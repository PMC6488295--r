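# Independent, unoptimized reference implementations used as oracles.
# These deliberately do not share code with the package internals: plain
# per-trial loops, and a dense 36,000-unit population vector.

oracle_signals <- function(sched) {
  err <- as.numeric(sched$block == "clamp")
  hit <- as.numeric(sched$hit == 1)
  list(err = err, te = err * (1 - hit), rew = hit)
}

oracle_motor_correction <- function(A, U, sched) {
  sig <- oracle_signals(sched)
  n <- nrow(sched)
  x <- numeric(n)
  for (i in seq_len(n - 1)) {
    x[i + 1] <- A * x[i] + if (sig$err[i] == 1) U else 0
  }
  x
}

oracle_adaptation_modulation <- function(A, U, gamma_A, gamma_u, sched) {
  sig <- oracle_signals(sched)
  n <- nrow(sched)
  x <- numeric(n)
  for (i in seq_len(n - 1)) {
    if (sig$rew[i] == 1) {
      x[i + 1] <- gamma_A * A * x[i] + if (sig$err[i] == 1) gamma_u * U else 0
    } else {
      x[i + 1] <- A * x[i] + if (sig$err[i] == 1) U else 0
    }
  }
  x
}

oracle_dual_error <- function(A_spe, U_spe, A_te, U_te, sched) {
  sig <- oracle_signals(sched)
  n <- nrow(sched)
  x_spe <- numeric(n)
  x_te <- numeric(n)
  for (i in seq_len(n - 1)) {
    x_spe[i + 1] <- A_spe * x_spe[i] + U_spe * sig$err[i]
    x_te[i + 1] <- A_te * x_te[i] + U_te * sig$te[i]
  }
  list(x_spe = x_spe, x_te = x_te, x = x_spe + x_te)
}

# dense population vector: every one of the 36,000 unit weights carried
# explicitly; direction grid at 0.01 degree resolution
oracle_reinforce_dense <- function(x, rew, A_prime, s,
                                   n_units = 36000) {
  dirs <- seq(-180, 180 - 360 / n_units, by = 360 / n_units)
  ux <- cos(dirs * pi / 180)
  uy <- sin(dirs * pi / 180)
  r <- numeric(n_units)
  n <- length(x)
  y <- numeric(n)
  V_l <- numeric(n)
  V_d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Vx <- sum(r * ux)
    Vy <- sum(r * uy)
    len <- sqrt(Vx^2 + Vy^2)
    if (len > 0) {
      vl <- min(1, len)
      vd <- atan2(Vy, Vx) * 180 / pi
      if (vd >= 180) vd <- vd - 360
      V_l[i] <- vl
      V_d[i] <- vd
      y[i] <- (1 - vl) * x[i] + vl * vd
    } else {
      y[i] <- x[i]
    }
    r <- A_prime * r
    if (rew[i] == 1) {
      theta <- sign(y[i]) * floor(abs(y[i]) * 100 + 0.5) / 100
      idx <- which.min(abs(dirs - theta))
      r[idx] <- r[idx] + s
    }
  }
  list(y = y, V_l = V_l, V_d = V_d)
}

oracle_movement_reinforcement <- function(A, U, A_prime, s, sched,
                                          dense = FALSE) {
  x <- oracle_motor_correction(A, U, sched)
  rew <- oracle_signals(sched)$rew
  if (dense) {
    oracle_reinforce_dense(x, rew, A_prime, s)
  } else {
    # sparse weights keyed by reinforced direction (still a literal
    # implementation of the update rule, independent of the package's
    # incremental components)
    n <- length(x)
    w <- numeric(0)
    wdir <- numeric(0)
    y <- numeric(n)
    for (i in seq_len(n)) {
      Vx <- sum(w * cos(wdir * pi / 180))
      Vy <- sum(w * sin(wdir * pi / 180))
      len <- sqrt(Vx^2 + Vy^2)
      if (len > 0) {
        vl <- min(1, len)
        vd <- atan2(Vy, Vx) * 180 / pi
        y[i] <- (1 - vl) * x[i] + vl * vd
      } else {
        y[i] <- x[i]
      }
      w <- A_prime * w
      if (rew[i] == 1) {
        theta <- sign(y[i]) * floor(abs(y[i]) * 100 + 0.5) / 100
        j <- match(theta, wdir)
        if (is.na(j)) {
          wdir <- c(wdir, theta)
          w <- c(w, s)
        } else {
          w[j] <- w[j] + s
        }
      }
    }
    y
  }
}

# a small mixed schedule with irregular blocks for oracle comparisons
random_schedule <- function(n_trials, seed) {
  set.seed(seed)
  blocks <- sample(c("baseline_nofb", "baseline_veridical", "clamp",
                     "zero_clamp", "washout_nofb"),
                   n_trials, replace = TRUE,
                   prob = c(0.1, 0.1, 0.6, 0.1, 0.1))
  hit <- ifelse(blocks == "clamp", rbinom(n_trials, 1, 0.5),
                ifelse(blocks == "zero_clamp", 1, 0))
  data.frame(trial = seq_len(n_trials),
             cycle = rep(seq_len(ceiling(n_trials / 4)),
                         each = 4)[seq_len(n_trials)],
             block = blocks,
             target_deg = rep(c(45, 135, 225, 315),
                              length.out = n_trials),
             clamp_deg = ifelse(blocks == "clamp", 1.75, 0),
             hit = hit)
}

# all-clamp schedule with a given outcome sequence, one target per cycle
outcome_schedule <- function(hits, e = 1.75) {
  n <- length(hits)
  data.frame(trial = seq_len(n), cycle = seq_len(n), block = "clamp",
             target_deg = 0, clamp_deg = e, hit = hits)
}

exhaustive_permutation_p <- function(g1, g2) {
  values <- c(g1, g2)
  n <- length(values)
  idx <- utils::combn(n, length(g1))
  obs <- abs(mean(g1) - mean(g2))
  stats <- apply(idx, 2, function(i) {
    abs(mean(values[i]) - mean(values[-i]))
  })
  mean(stats >= obs - 1e-12)
}
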