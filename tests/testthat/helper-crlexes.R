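crl_actions_for_test <- function() c("go_high", "go_low", "none")

# Shared fixtures and the R-level reference implementation of the dynamic
# round, written only from the exported ops. The engine test holds the C++
# inner loop to this reference step for step.

test_arena <- function(...) {
  arena_config(...)
}

# Reference dynamic round: replicates play_round_dynamic() including its RNG
# draw order (spot allocation coin, heading jitter for a then b, then per
# step: agent a's sensors/command/noise, agent b's, simultaneous move).
reference_round_dynamic <- function(action_a, action_b, payoff,
                                    arena = arena_config(), f = 0.3,
                                    ablation = "full") {
  high_first <- runif(1) < 0.5
  spot_high <- arena$spot_positions[[if (high_first) 1L else 2L]]
  spot_low <- arena$spot_positions[[if (high_first) 2L else 1L]]
  full_mask <- inhibition_for("none")
  mask_a <- if (ablation == "reactive_only") full_mask else
    inhibition_for(action_a)
  mask_b <- if (ablation == "reactive_only") full_mask else
    inhibition_for(action_b)
  pose_a <- arena$agent_start_poses[[1]]
  pose_b <- arena$agent_start_poses[[2]]
  if (arena$heading_jitter > 0) {
    j <- arena$heading_jitter
    pose_a[3] <- crlexes:::wrap_angle(pose_a[3] + runif(1, -j, j))
    pose_b[3] <- crlexes:::wrap_angle(pose_b[3] + runif(1, -j, j))
  }
  steps <- 0L
  traj <- matrix(NA_real_, arena$max_steps, 6)
  verdict <- list(kind = "timeout")
  repeat {
    sa <- read_sensors(pose_a, pose_b, spot_high, spot_low, arena)
    ca <- combine_behaviors(sa, mask_a, f, arena$m_min, arena$m_max)
    ca <- pmin(pmax(ca + rnorm(2, 0, arena$motor_noise_sd), arena$m_min),
               arena$m_max)
    sb <- read_sensors(pose_b, pose_a, spot_high, spot_low, arena)
    cb <- combine_behaviors(sb, mask_b, f, arena$m_min, arena$m_max)
    cb <- pmin(pmax(cb + rnorm(2, 0, arena$motor_noise_sd), arena$m_min),
               arena$m_max)
    new_a <- step_kinematics(pose_a, ca, arena)
    new_b <- step_kinematics(pose_b, cb, arena)
    pose_a <- new_a
    pose_b <- new_b
    steps <- steps + 1L
    traj[steps, ] <- c(pose_a, pose_b)
    v <- check_round_end(pose_a, pose_b, spot_high, spot_low, arena, steps)
    if (v$kind != "none") {
      verdict <- v
      break
    }
  }
  list(steps = steps, verdict = verdict, pose_a = pose_a, pose_b = pose_b,
       traj = traj[seq_len(steps), , drop = FALSE],
       spot_high = spot_high, spot_low = spot_low)
}

# Exact outcome distribution of one ballistic round for fixed policies:
# enumerate the 3x3 joint actions and the none-coin.
ballistic_oracle_distribution <- function(p_a, p_b) {
  # spot-choice distribution implied by an action distribution
  spot_prob <- function(p) c(high = unname(p["go_high"] + p["none"] / 2),
                             low = unname(p["go_low"] + p["none"] / 2))
  sa <- spot_prob(p_a)
  sb <- spot_prob(p_b)
  c(tie = sa["high"] * sb["high"] + sa["low"] * sb["low"],
    a_high = sa["high"] * sb["low"],
    b_high = sa["low"] * sb["high"]) |> unname() |>
    stats::setNames(c("tie", "a_high", "b_high"))
}

# Plain-arithmetic replay of an actor-critic transcript, independent of the
# package's update functions.
replay_learner <- function(transcript, gamma = 0.40, eta = 0.15,
                           delta = 0.45) {
  V <- c(high = 0, low = 0, tie = 0)
  C <- matrix(0, 3, 3, dimnames = list(c("go_high", "go_low", "none"),
                                       c("high", "low", "tie")))
  for (i in seq_len(nrow(transcript))) {
    tr <- transcript[i, ]
    e <- tr$r + gamma * V[[tr$s_t]] - V[[tr$s_prev]]
    V[[tr$s_prev]] <- V[[tr$s_prev]] + eta * e
    C[tr$a, tr$s_prev] <- max(0, C[tr$a, tr$s_prev] + delta * e)
  }
  list(V = V, C = C, P = t(t(C + 1) / (colSums(C) + 3)))
}

# Small synthetic one-dyad log with a prescribed outcome sequence.
# outcomes: character vector of "a", "b", "t" (a wins high / b wins high /
# tie), payoffs default to the high preset.
synthetic_log <- function(outcomes, a = 4, b = 1) {
  n <- length(outcomes)
  tie <- outcomes == "t"
  state_a <- ifelse(tie, "tie", ifelse(outcomes == "a", "high", "low"))
  state_b <- ifelse(tie, "tie", ifelse(outcomes == "b", "high", "low"))
  tibble::tibble(
    dyad_id = 1L, condition = "synthetic", mode = "ballistic",
    payoff_a = a, payoff_b = b, ablation = "full", seed = 0L,
    round = seq_len(n), action_a = "none", action_b = "none",
    state_a = state_a, state_b = state_b,
    reward_a = ifelse(tie, 0, ifelse(outcomes == "a", a, b)),
    reward_b = ifelse(tie, 0, ifelse(outcomes == "b", a, b)),
    tie = tie, steps = 0L,
    none_a = TRUE, none_b = TRUE)
}
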