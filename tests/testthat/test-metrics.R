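test_that("efficiency is the collective reward fraction and 1 - tie rate", {
  expect_equal(efficiency(synthetic_log(rep("a", 10))), 1)
  expect_equal(efficiency(synthetic_log(rep("t", 10))), 0)
  expect_equal(efficiency(synthetic_log(rep(c("a", "t"), 30))), 0.5)

  set.seed(20)
  for (i in 1:10) {
    log <- synthetic_log(sample(c("a", "b", "t"), 40, replace = TRUE),
                         a = sample(c(2, 4, 8), 1))
    expect_equal(efficiency(log), 1 - mean(log$tie))
  }
  expect_error(efficiency(synthetic_log(character(0))), "empty")
})

test_that("fairness measures the balance of high-reward acquisitions", {
  expect_equal(fairness(synthetic_log(rep(c("a", "b"), 10))), 1)
  expect_equal(fairness(synthetic_log(rep("a", 10))), 0)
  expect_equal(fairness(synthetic_log(c(rep("a", 6), rep("b", 4)))), 0.8)
  expect_warning(f <- fairness(synthetic_log(rep("t", 10))), "undefined")
  expect_true(is.na(f))
})

test_that("surprisal uses a windowed add-one estimator in bits", {
  # empty history: uniform over the 3-symbol alphabet
  s <- surprisal_series(synthetic_log("a"))
  expect_equal(s, log2(3))
  expect_equal(s, 1.585, tolerance = 1e-3)

  # a full window of identical outcomes makes the next one cheap
  s <- surprisal_series(synthetic_log(rep("a", 9)))
  expect_equal(s[9], -log2(9 / 11))
  expect_equal(s[9], 0.2895, tolerance = 1e-4)

  # the first unseen symbol after a full window costs the ceiling exactly
  s <- surprisal_series(synthetic_log(c(rep("a", 8), "b")))
  expect_equal(s[9], log2(8 + 3))

  # every value respects the add-one bounds
  set.seed(30)
  for (i in 1:10) {
    log <- synthetic_log(sample(c("a", "b", "t"), 50, replace = TRUE))
    s <- surprisal_series(log)
    expect_true(all(s >= -log2((8 + 1) / (8 + 3)) - 1e-12))
    expect_true(all(s <= log2(8 + 3) + 1e-12))
  }

  # pure dominance is more predictable than strict alternation, and both
  # beat the uniform baseline
  dom <- stability(synthetic_log(rep("a", 40)))
  alt <- stability(synthetic_log(rep(c("a", "b"), 20)))
  expect_lt(dom, alt)
  expect_lt(alt, log2(3))

  # without smoothing a repeated outcome is eventually free
  s <- surprisal_series(synthetic_log(rep("a", 10)), smoothing = FALSE)
  expect_equal(s[10], 0)
})

test_that("reliance on the adaptive layer counts non-none agent-rounds", {
  log <- synthetic_log(rep("a", 10))   # all none by construction
  expect_equal(reliance_al(log), 0)
  log$action_a <- rep(c("go_high", "none"), 5)
  log$action_b <- "go_low"
  expect_equal(reliance_al(log), 15 / 20)
})

test_that("convention classification labels the trailing non-tie rounds", {
  expect_identical(classify_convention(synthetic_log(rep(c("a", "b"), 15))),
                   "turn_taking")
  expect_identical(classify_convention(synthetic_log(c(rep("t", 10),
                                                       rep("a", 25)))),
                   "dominance")
  expect_identical(classify_convention(synthetic_log(c("a", "b", rep("t", 20)))),
                   "none")
  # i.i.d. uniform winners are (almost) never classified as a convention
  set.seed(40)
  labels <- replicate(50, {
    classify_convention(synthetic_log(sample(c("a", "b"), 30,
                                             replace = TRUE)))
  })
  expect_gt(mean(labels == "none"), 0.9)
})

test_that("metrics are symmetric under swapping the agent labels", {
  set.seed(50)
  log <- synthetic_log(sample(c("a", "b", "t"), 60, replace = TRUE))
  swapped <- log
  swapped[c("state_a", "state_b")] <- log[c("state_b", "state_a")]
  swapped[c("reward_a", "reward_b")] <- log[c("reward_b", "reward_a")]
  swapped[c("action_a", "action_b")] <- log[c("action_b", "action_a")]
  expect_equal(efficiency(swapped), efficiency(log))
  expect_equal(fairness(swapped), fairness(log))
  expect_equal(stability(swapped), stability(log))
  expect_equal(reliance_al(swapped), reliance_al(log))
})

test_that("dyad metrics aggregate per dyad and summarize per condition", {
  plan <- experiment_plan(list(game_condition("ballistic", "high",
                                              rounds = 20)),
                          dyads = 6, seed = 42)
  res <- run_grid(plan)
  expect_identical(nrow(res$dyads), 6L)
  expect_true(all(res$dyads$efficiency >= 0 & res$dyads$efficiency <= 1))
  expect_true(all(res$dyads$stability >= 0))
  expect_true(all(res$dyads$reliance_al >= 0 & res$dyads$reliance_al <= 1))
  expect_true(all(res$summary$metric %in%
                    c("efficiency", "fairness", "stability", "reliance_al")))
  expect_true(all(res$summary$n <= 6))

  # an all-tie dyad is dropped from fairness aggregation with a message
  log <- synthetic_log(rep("t", 10))
  log_b <- synthetic_log(rep(c("a", "b"), 5))
  log_b$dyad_id <- 2L
  m <- dyad_metrics(dplyr::bind_rows(log, log_b))
  expect_true(is.na(m$fairness[m$dyad_id == 1]))
  expect_message(s <- condition_summary(m), "all-tie")
  expect_identical(s$n[s$metric == "fairness"], 1L)
})
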