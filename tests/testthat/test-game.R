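test_that("ballistic rounds resolve the bare matrix game", {
  pay <- payoff_preset("high")

  out <- play_round_ballistic("go_high", "go_high", pay)
  expect_true(out$tie)
  expect_identical(c(out$reward_a, out$reward_b), c(0, 0))
  expect_identical(c(out$state_a, out$state_b), c("tie", "tie"))

  out <- play_round_ballistic("go_high", "go_low", pay)
  expect_false(out$tie)
  expect_identical(c(out$reward_a, out$reward_b), c(4, 1))
  expect_identical(c(out$state_a, out$state_b), c("high", "low"))

  # both none: tie with probability exactly 1/2 (coin enumeration)
  set.seed(5)
  n <- 4000
  ties <- mean(replicate(n, play_round_ballistic("none", "none", pay)$tie))
  expect_lt(abs(ties - 0.5), 3 * sqrt(0.25 / n))
})

test_that("ballistic mode equals the brute-force matrix-game oracle", {
  p_a <- c(go_high = 0.5, go_low = 0.3, none = 0.2)
  p_b <- c(go_high = 0.2, go_low = 0.5, none = 0.3)
  want <- ballistic_oracle_distribution(p_a, p_b)

  pay <- payoff_preset("low")
  set.seed(8)
  n <- 6000
  sym <- replicate(n, {
    out <- play_round_ballistic(sample(names(p_a), 1, prob = p_a),
                                sample(names(p_b), 1, prob = p_b), pay)
    if (out$tie) "tie" else if (out$state_a == "high") "a_high" else "b_high"
  })
  for (o in names(want)) {
    se <- sqrt(want[[o]] * (1 - want[[o]]) / n)
    expect_lt(abs(mean(sym == o) - want[[o]]), 4 * se)
  }
})

test_that("every round conserves reward: a + b when resolved, zero on ties", {
  cond <- game_condition("ballistic", "high", rounds = 40)
  log <- play_dyad(cond, seed = 3)
  total <- log$reward_a + log$reward_b
  expect_true(all(total[!log$tie] == 5))
  expect_true(all(total[log$tie] == 0))
  expect_true(all(log$tie == (log$state_a == "tie")))
  expect_true(all(log$tie == (log$state_b == "tie")))
  expect_true(all(xor(log$state_a == "high", log$state_b == "high") |
                    log$tie))

  arena <- arena_config(max_steps = 450)
  cond <- game_condition("dynamic", "low", rounds = 12)
  log <- play_dyad(cond, seed = 4, arena = arena)
  total <- log$reward_a + log$reward_b
  expect_true(all(total[!log$tie] == 3))
  expect_true(all(total[log$tie] == 0))
})

test_that("dyads are deterministic given (condition, seed)", {
  for (cond in list(game_condition("ballistic", "high", rounds = 25),
                    game_condition("dynamic", "low", rounds = 6),
                    game_condition("dynamic", "high", rounds = 6,
                                   ablation = "reactive_only"))) {
    l1 <- play_dyad(cond, seed = 71)
    l2 <- play_dyad(cond, seed = 71)
    expect_identical(as.data.frame(l1), as.data.frame(l2))
  }
  # and the caller's RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(play_dyad(game_condition("ballistic", "low",
                                                  rounds = 5), seed = 2))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("a zero-round condition yields an empty log", {
  log <- play_dyad(game_condition("ballistic", "high", rounds = 0), seed = 1)
  expect_identical(nrow(log), 0L)
})

test_that("adaptive-only ablation in dynamic mode plays the ballistic game", {
  ball <- play_dyad(game_condition("ballistic", "high", rounds = 30),
                    seed = 55)
  adap <- play_dyad(game_condition("dynamic", "high", rounds = 30,
                                   ablation = "adaptive_only"), seed = 55)
  cols <- c("round", "action_a", "action_b", "state_a", "state_b",
            "reward_a", "reward_b", "tie")
  expect_identical(as.data.frame(ball[cols]), as.data.frame(adap[cols]))
  expect_true(all(adap$steps == 0L))
})

test_that("the C++ round engine reproduces the R reference loop exactly", {
  arena <- arena_config(max_steps = 500)
  pay <- payoff_preset("high")
  for (acts in list(c("go_high", "go_low"), c("none", "none"),
                    c("go_high", "none"))) {
    seed <- 1234 + match(acts[1], c("go_high", "none"))
    set.seed(seed)
    got <- play_round_dynamic(acts[1], acts[2], pay, arena, record = TRUE)
    set.seed(seed)
    ref <- reference_round_dynamic(acts[1], acts[2], pay, arena)
    expect_identical(got$steps, ref$steps)
    expect_equal(unname(got$trajectory[, 1:3]),
                 unname(ref$traj[, 1:3]), tolerance = 1e-12)
    expect_equal(unname(got$trajectory[, 4:6]),
                 unname(ref$traj[, 4:6]), tolerance = 1e-12)
  }
})

test_that("dynamic outcome labeling follows the tie-circle rule", {
  arena <- arena_config()
  pay <- payoff_preset("high")

  # complementary commitments almost always split the spots
  set.seed(12)
  outs <- replicate(60, {
    r <- play_round_dynamic("go_high", "go_low", pay, arena)
    c(tie = r$tie, a_high = r$state_a == "high", steps = r$steps)
  })
  expect_lt(mean(outs["tie", ]), 0.2)
  expect_gt(mean(outs["a_high", !as.logical(outs["tie", ])]), 0.9)
  expect_true(all(outs["steps", ] > 0))

  # same commitment contests the same spot: almost always a tie
  set.seed(13)
  ties <- replicate(60, play_round_dynamic("go_high", "go_high", pay,
                                           arena)$tie)
  expect_gt(mean(ties), 0.7)

  # timeout scores as a tie
  tiny <- arena_config(max_steps = 5)
  set.seed(14)
  r <- play_round_dynamic("go_high", "go_low", pay, tiny)
  expect_true(r$tie)
  expect_identical(r$steps, 5L)

  # collision avoidance resolves same-spot contests it can sense: paired
  # seeds, both agents committed to the high spot, partner within sensing
  # range, against an avoidance-blind control
  on_cfg <- arena_config(agent_start_poses = list(c(9.2, 2, pi / 2),
                                                  c(10.8, 2, pi / 2)),
                         sensor_range_agent = 6)
  off_cfg <- arena_config(agent_start_poses = list(c(9.2, 2, pi / 2),
                                                   c(10.8, 2, pi / 2)),
                          sensor_range_agent = 1e-6)
  tie_on <- tie_off <- logical(200)
  for (i in seq_len(200)) {
    set.seed(9000 + i)
    tie_on[i] <- play_round_dynamic("go_high", "go_high", pay, on_cfg)$tie
    set.seed(9000 + i)
    tie_off[i] <- play_round_dynamic("go_high", "go_high", pay, off_cfg)$tie
  }
  expect_lt(mean(tie_on), mean(tie_off))
})

test_that("round logs survive a CSV round trip with their config sidecar", {
  log <- play_dyad(game_condition("ballistic", "low", rounds = 15), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dyad_log(log, path, config = list(seed = 9, note = "fixture"))
  back <- read_dyad_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log), ignore_attr = TRUE)
  expect_equal(attr(back, "config")$seed, 9)
})
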