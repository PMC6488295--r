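test_that("motor-correction recursion matches closed forms and the oracle", {
  long <- outcome_schedule(rep(0, 1000), e = 3.5)
  tr <- simulate_motor_correction(state_space_params(0.9, 1), long)
  expect_equal(tail(tr$x, 1), 10, tolerance = 1e-6)  # U / (1 - A)
  expect_equal(tr$x[3], 1.9)                         # x(2)=1, x(3)=0.9+1
  expect_true(all(tr$y == tr$x))

  # U -> 0 (fit lower bound): no learning
  flat <- simulate_motor_correction(list(A = 0.9, U = 1e-12), long)
  expect_true(all(abs(flat$x) < 1e-8))

  for (seed in 1:5) {
    sched <- random_schedule(200, seed)
    A <- runif(1, 0.5, 0.99)
    U <- runif(1, 0.05, 1.5)
    tr <- simulate_motor_correction(list(A = A, U = U), sched)
    expect_lt(max(abs(tr$x - oracle_motor_correction(A, U, sched))), 1e-9)
  }
})

test_that("adaptation-modulation gains act only on hit trials", {
  d3 <- build_design("exp3_straddle_to_hit", seed = 2)
  mp <- modulation_params(0.95, 0.4, 0.98, 0.5)

  # gain identity: gamma = 1 reduces exactly to motor correction
  same <- simulate_adaptation_modulation(
    modulation_params(0.95, 0.4, 1, 1), d3)
  base <- simulate_motor_correction(state_space_params(0.95, 0.4), d3)
  expect_identical(same$x, base$x)

  # all-hit steady state: gamma_u * U / (1 - gamma_A * A)
  allhit <- outcome_schedule(rep(1, 3000))
  tr <- simulate_adaptation_modulation(modulation_params(0.9, 1, 1, 0.5),
                                       allhit)
  expect_equal(tail(tr$x, 1), 5, tolerance = 1e-6)
  expect_equal(steady_state("adaptation_modulation",
                            list(A = 0.9, U = 1, gamma_A = 1, gamma_u = 0.5),
                            "all_hit"), 5)

  for (seed in 6:10) {
    sched <- random_schedule(200, seed)
    p <- list(A = runif(1, 0.5, 0.99), U = runif(1, 0.05, 1),
              gamma_A = runif(1, 0.5, 1.2), gamma_u = runif(1, 0.2, 1.2))
    tr <- simulate_adaptation_modulation(p, sched)
    want <- oracle_adaptation_modulation(p$A, p$U, p$gamma_A, p$gamma_u,
                                         sched)
    expect_lt(max(abs(tr$x - want)), 1e-9)
  }
})

test_that("dual-error model sums an SPE and a TE process", {
  # all-hit: TE never present, identical to motor correction
  allhit <- outcome_schedule(rep(1, 500))
  dp <- dual_error_params(0.9, 0.6, 0.95, 0.3)
  tr <- simulate_dual_error(dp, allhit)
  mc <- simulate_motor_correction(state_space_params(0.9, 0.6), allhit)
  expect_identical(tr$y, mc$y)
  expect_true(all(tr$x_te == 0))

  # all-miss steady state: sum of the two fixed points
  allmiss <- outcome_schedule(rep(0, 4000))
  tr2 <- simulate_dual_error(dual_error_params(0.9, 0.5, 0.9, 0.5), allmiss)
  expect_equal(tail(tr2$y, 1), 10, tolerance = 1e-6)
  expect_equal(steady_state("dual_error",
                            list(A_spe = 0.9, U_spe = 0.5, A_te = 0.9,
                                 U_te = 0.5), "all_miss"), 10)

  # post-transfer: x_te decays geometrically at rate A_te, y -> SPE fixed pt
  transfer <- outcome_schedule(c(rep(0, 2000), rep(1, 400)))
  tr3 <- simulate_dual_error(dual_error_params(0.95, 0.3, 0.9, 0.4),
                             transfer)
  te_at_switch <- tr3$x_te[2001]
  post <- tr3$x_te[2001:2400]
  expect_equal(post, te_at_switch * 0.9^(0:399), tolerance = 1e-9)
  expect_equal(tail(tr3$y, 1), 0.3 / (1 - 0.95), tolerance = 1e-3)

  for (seed in 11:15) {
    sched <- random_schedule(200, seed)
    p <- list(A_spe = runif(1, 0.5, 0.99), U_spe = runif(1, 0.05, 1),
              A_te = runif(1, 0.5, 0.99), U_te = runif(1, 0.05, 1))
    tr <- simulate_dual_error(p, sched)
    want <- oracle_dual_error(p$A_spe, p$U_spe, p$A_te, p$U_te, sched)
    expect_lt(max(abs(tr$y - want$x)), 1e-9)
    expect_lt(max(abs(tr$x_spe - want$x_spe)), 1e-9)
  }
})

test_that("movement reinforcement matches the dense 36,000-unit oracle", {
  # small schedule so the dense population vector is affordable
  sched <- outcome_schedule(rbinom(40, 1, 0.6))
  set.seed(42)
  for (i in 1:3) {
    A <- runif(1, 0.7, 0.95); U <- runif(1, 0.2, 1)
    Ap <- runif(1, 0.8, 0.999); s <- runif(1, 0.02, 0.3)
    tr <- simulate_movement_reinforcement(list(A = A, U = U),
                                          list(A_prime = Ap, s = s), sched)
    dense <- oracle_reinforce_dense(oracle_motor_correction(A, U, sched),
                                    oracle_signals(sched)$rew, Ap, s)
    expect_lt(max(abs(tr$y - dense$y)), 1e-9)
    expect_lt(max(abs(tr$V_l - dense$V_l)), 1e-9)
  }
})

test_that("movement reinforcement: limits and the sparse oracle agree", {
  # s -> 0: no reinforcement, y == x throughout
  sched <- random_schedule(150, 21)
  tr <- simulate_movement_reinforcement(list(A = 0.9, U = 0.8),
                                        list(A_prime = 0.95, s = 1e-300),
                                        sched)
  expect_equal(tr$y, tr$x, tolerance = 1e-12)

  # all-miss schedule: weights never grow, y == x for any s
  miss <- outcome_schedule(rep(0, 300))
  tr2 <- simulate_movement_reinforcement(list(A = 0.9, U = 0.8),
                                         list(A_prime = 0.9, s = 0.5), miss)
  expect_identical(tr2$y, tr2$x)
  expect_true(all(tr2$V_l == 0))

  # three all-hit trials against the hand-unrolled sparse oracle
  hit3 <- outcome_schedule(rep(1, 3))
  tr3 <- simulate_movement_reinforcement(list(A = 0.9, U = 1),
                                         list(A_prime = 0.99, s = 0.1), hit3)
  want <- oracle_movement_reinforcement(0.9, 1, 0.99, 0.1, hit3)
  expect_lt(max(abs(tr3$y - want)), 1e-12)

  # longer mixed schedules against the sparse literal implementation
  for (seed in 31:33) {
    sched <- random_schedule(200, seed)
    tr <- simulate_movement_reinforcement(list(A = 0.92, U = 0.5),
                                          list(A_prime = 0.97, s = 0.15),
                                          sched)
    want <- oracle_movement_reinforcement(0.92, 0.5, 0.97, 0.15, sched)
    expect_lt(max(abs(tr$y - want)), 1e-9)
  }

  # V_l is clipped to 1 under heavy reinforcement
  heavy <- simulate_movement_reinforcement(list(A = 0.9, U = 0.5),
                                           list(A_prime = 0.999, s = 0.9),
                                           outcome_schedule(rep(1, 200)))
  expect_true(max(heavy$V_l) <= 1)
  expect_equal(max(heavy$V_l), 1)
})

test_that("hybrid reductions are exact", {
  d3 <- build_design("exp3_hit_to_straddle", seed = 5)
  p_am <- list(A = 0.95, U = 0.4, gamma_A = 0.99, gamma_u = 0.5)
  p_de <- list(A_spe = 0.95, U_spe = 0.3, A_te = 0.97, U_te = 0.2)

  # s -> 0 recovers the core models exactly
  h1 <- simulate_hybrid("mr_am", c(p_am, A_prime = 0.9, s = 1e-300), d3)
  am <- simulate_adaptation_modulation(p_am, d3)
  expect_identical(h1$y, am$y)

  h2 <- simulate_hybrid("mr_de", c(p_de, A_prime = 0.9, s = 1e-300), d3)
  de <- simulate_dual_error(p_de, d3)
  expect_identical(h2$y, de$y)

  # gains = 1 recovers movement reinforcement exactly
  h3 <- simulate_hybrid("mr_am", list(A = 0.95, U = 0.4, gamma_A = 1,
                                      gamma_u = 1, A_prime = 0.98, s = 0.1),
                        d3)
  mr <- simulate_movement_reinforcement(list(A = 0.95, U = 0.4),
                                        list(A_prime = 0.98, s = 0.1), d3)
  expect_identical(h3$y, mr$y)
})

test_that("trajectories converge under a constant regime", {
  sched <- outcome_schedule(rep(0, 2000))
  for (p in list(list(A = 0.9, U = 1), list(A = 0.99, U = 0.2))) {
    tr <- simulate_motor_correction(p, sched)
    expect_lt(abs(diff(tail(tr$x, 2))), 1e-8)
  }
  trd <- simulate_dual_error(list(A_spe = 0.95, U_spe = 0.4, A_te = 0.9,
                                  U_te = 0.3), sched)
  expect_lt(abs(diff(tail(trd$y, 2))), 1e-8)
})

test_that("steady_state covers every model and rejects undefined regimes", {
  expect_equal(steady_state("motor_correction", list(A = 0.9, U = 1),
                            "all_miss"), 10)
  expect_equal(steady_state("dual_error",
                            list(A_spe = 0.9, U_spe = 0.5, A_te = 0.9,
                                 U_te = 0.5), "all_hit"), 5)
  expect_equal(steady_state("movement_reinforcement", list(A = 0.9, U = 1),
                            "all_miss"), 10)
  expect_error(steady_state("movement_reinforcement", list(A = 0.9, U = 1),
                            "all_hit"), class = "unsupported_regime_error")
  expect_error(steady_state("mr_am", list(A = 0.9, U = 1), "all_hit"),
               class = "unsupported_regime_error")
  expect_error(steady_state("nope", list(A = 0.9, U = 1), "all_miss"),
               class = "unknown_model_error")
})

test_that("parameter bundles reject out-of-domain values", {
  expect_error(state_space_params(1.2, 0.5), class = "parameter_domain_error")
  expect_error(state_space_params(0.9, -1), class = "parameter_domain_error")
  expect_error(state_space_params(0.9, 2, e = 1.75),
               class = "parameter_domain_error")
  expect_error(reinforcement_params(0.9, 0), class = "parameter_domain_error")
  expect_error(modulation_params(0.9, 0.5, -1, 1),
               class = "parameter_domain_error")
  expect_error(dual_error_params(0.9, 0.5, 1.5, 0.5),
               class = "parameter_domain_error")
})

test_that("transfer signatures discriminate the models", {
  # miss asymptote then hit: movement reinforcement never drops; the
  # gain-modulation (gamma_u < 1) and dual-error models drop by their
  # closed-form amounts
  transfer <- outcome_schedule(c(rep(0, 960), rep(1, 640)))
  pre_idx <- 960
  set.seed(99)
  for (i in 1:20) {
    # asymptote kept within the directional range (see methods vignette)
    A <- runif(1, 0.5, 0.995); U <- runif(1, 0.05, min(1.7, 60 * (1 - A)))
    Ap <- runif(1, 0.05, 0.995); s <- runif(1, 0.01, 0.95)
    tr <- simulate_movement_reinforcement(list(A = A, U = U),
                                          list(A_prime = Ap, s = s),
                                          transfer)
    expect_gte(tail(tr$y, 1), tr$y[pre_idx] - 0.1)
  }

  am <- simulate_adaptation_modulation(
    list(A = 0.95, U = 0.4, gamma_A = 1, gamma_u = 0.4), transfer)
  pre <- am$x[pre_idx]
  expect_lt(tail(am$x, 1), pre)
  expect_equal(tail(am$x, 1), 0.4 * 0.4 / (1 - 0.95), tolerance = 1e-6)

  de <- simulate_dual_error(
    list(A_spe = 0.95, U_spe = 0.3, A_te = 0.9, U_te = 0.3), transfer)
  expect_lt(tail(de$y, 1), de$y[pre_idx])
  expect_equal(tail(de$y, 1), 0.3 / (1 - 0.95), tolerance = 1e-6)
})
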