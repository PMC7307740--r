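#' Payoff scheme of the anti-coordination game
#'
#' A round won alone at the high spot pays `a`, the agent at the other spot
#' earns `b`, and a contested round (tie) pays both agents 0. Presets:
#' `payoff_preset("low")` is (2, 1), `payoff_preset("high")` is (4, 1); the
#' payoff sweep additionally uses (1,1) through (32,1).
#'
#' @param a High-spot payoff, `a >= b`.
#' @param b Low-spot payoff, `b > 0`.
#' @return An object of class `crl_payoff`.
#' @export
payoff_scheme <- function(a, b = 1) {
  stopifnot(a >= b, b > 0)
  structure(list(a = a, b = b), class = "crl_payoff")
}

#' @rdname payoff_scheme
#' @param name `"low"` or `"high"`.
#' @export
payoff_preset <- function(name = c("low", "high")) {
  name <- match.arg(name)
  if (name == "low") payoff_scheme(2, 1) else payoff_scheme(4, 1)
}

#' Define one experimental condition
#'
#' @param mode `"ballistic"` (rounds resolved as the discrete matrix game)
#'   or `"dynamic"` (rounds played out in the continuous arena).
#' @param payoff `"high"`, `"low"`, or a [payoff_scheme()].
#' @param rounds Rounds per dyad. Defaults to 50 for the high preset and 60
#'   for the low preset (50 otherwise).
#' @param ablation `"full"`, `"reactive_only"` (adaptive layer disabled; no
#'   action selection, inhibition or learning) or `"adaptive_only"` (rounds
#'   resolved ballistically even in dynamic mode).
#' @param label Condition label used in logs; built from the arguments when
#'   omitted.
#' @return An object of class `crl_condition`.
#' @export
#' @examples
#' game_condition("dynamic", "high")
game_condition <- function(mode = c("dynamic", "ballistic"),
                           payoff = "high", rounds = NULL,
                           ablation = c("full", "reactive_only",
                                        "adaptive_only"),
                           label = NULL) {
  mode <- match.arg(mode)
  ablation <- match.arg(ablation)
  payoff_name <- NULL
  if (is.character(payoff)) {
    payoff_name <- match.arg(payoff, c("low", "high"))
    payoff <- payoff_preset(payoff_name)
  }
  stopifnot(inherits(payoff, "crl_payoff"))
  if (is.null(rounds))
    rounds <- if (identical(payoff_name, "low")) 60L else 50L
  rounds <- as.integer(rounds)
  stopifnot(rounds >= 0L)
  if (is.null(label)) {
    label <- paste0(mode, "_",
                    if (!is.null(payoff_name)) payoff_name
                    else paste0(payoff$a, "v", payoff$b))
    if (ablation != "full") label <- paste0(label, "_", ablation)
  }
  structure(list(mode = mode, payoff = payoff, rounds = rounds,
                 ablation = ablation, label = label),
            class = "crl_condition")
}

# Map an action to a spot choice; "none" flips a fair coin.
ballistic_choice <- function(action) {
  switch(action,
         go_high = "high",
         go_low = "low",
         none = if (runif(1) < 0.5) "high" else "low")
}

#' Resolve one round in ballistic mode
#'
#' The round is the bare matrix game: each action maps to a spot (the
#' `none` action picks one uniformly at random), identical choices are a
#' tie worth 0 to both, and different choices pay each agent its chosen
#' spot's reward.
#'
#' @param action_a,action_b Round actions of the two agents.
#' @param payoff A [payoff_scheme()].
#' @return List with `state_a`, `state_b`, `reward_a`, `reward_b`, `tie`,
#'   `steps` (always 0: no embodiment).
#' @export
play_round_ballistic <- function(action_a, action_b, payoff) {
  ca <- ballistic_choice(action_a)
  cb <- ballistic_choice(action_b)
  if (ca == cb)
    return(list(state_a = "tie", state_b = "tie",
                reward_a = 0, reward_b = 0, tie = TRUE, steps = 0L))
  list(state_a = ca, state_b = cb,
       reward_a = if (ca == "high") payoff$a else payoff$b,
       reward_b = if (cb == "high") payoff$a else payoff$b,
       tie = FALSE, steps = 0L)
}

#' Play one round in the continuous arena
#'
#' At the start of the round the high reward is assigned uniformly at
#' random to one of the two spot positions, each agent's inhibition mask is
#' fixed by its action, and the sensorimotor loop (sense, combine
#' behaviors, integrate kinematics, both agents each step) runs until an
#' agent reaches a spot or the step cap is hit. When the first agent
#' reaches a spot, the round is a tie if the other agent is inside that
#' spot's tie circle; otherwise the reacher earns its spot's payoff and the
#' other agent the other spot's. Both agents reaching different spots on
#' the same step is successful anti-coordination (each earns its own
#' spot); reaching the same spot on the same step is a tie. A timeout
#' scores as a tie with reward 0.
#'
#' @param action_a,action_b Round actions (ignored by the reactive-only
#'   ablation, which keeps every behavior active).
#' @param payoff A [payoff_scheme()].
#' @param arena An [arena_config()].
#' @param f Forward speed constant of the reactive layer.
#' @param ablation `"full"` or `"reactive_only"`.
#' @param record Keep the step-by-step poses (for plotting).
#' @return As [play_round_ballistic()], plus `steps` actually elapsed and,
#'   if `record`, a `trajectory` matrix with columns
#'   `xa, ya, tha, xb, yb, thb`.
#' @export
play_round_dynamic <- function(action_a, action_b, payoff,
                               arena = arena_config(), f = 0.3,
                               ablation = "full", record = FALSE) {
  high_first <- runif(1) < 0.5
  spot_high <- arena$spot_positions[[if (high_first) 1L else 2L]]
  spot_low <- arena$spot_positions[[if (high_first) 2L else 1L]]
  full_mask <- inhibition_for("none")
  mask_a <- if (ablation == "reactive_only") full_mask else
    inhibition_for(action_a)
  mask_b <- if (ablation == "reactive_only") full_mask else
    inhibition_for(action_b)

  start_a <- arena$agent_start_poses[[1]]
  start_b <- arena$agent_start_poses[[2]]
  if (arena$heading_jitter > 0) {
    j <- arena$heading_jitter
    start_a[3] <- wrap_angle(start_a[3] + runif(1, -j, j))
    start_b[3] <- wrap_angle(start_b[3] + runif(1, -j, j))
  }
  res <- run_round_cpp(
    start_a, start_b,
    spot_high, spot_low,
    mask_a$high_seek_active, mask_a$low_seek_active,
    mask_b$high_seek_active, mask_b$low_seek_active,
    f, arena$sensor_range_high, arena$sensor_range_low,
    arena$sensor_range_agent,
    arena$sensor_halfangle, arena$dt, arena$speed_scale,
    arena$wheelbase, arena$agent_radius, arena$width, arena$height,
    arena$spot_reach_radius, arena$max_steps, arena$motor_noise_sd,
    arena$m_min, arena$m_max, record)

  out <- resolve_dynamic(res, spot_high, spot_low, payoff, arena)
  out$steps <- res$steps
  if (record) {
    traj <- res$traj
    colnames(traj) <- c("xa", "ya", "tha", "xb", "yb", "thb")
    out$trajectory <- traj
  }
  out
}

# Outcome labeling from the engine's termination record.
resolve_dynamic <- function(res, spot_high, spot_low, payoff, arena) {
  tie_out <- list(state_a = "tie", state_b = "tie",
                  reward_a = 0, reward_b = 0, tie = TRUE)
  if (isTRUE(res$timeout)) return(tie_out)
  r <- res$reached # a_high, b_high, a_low, b_low
  a_spot <- if (r[1]) "high" else if (r[3]) "low" else NA_character_
  b_spot <- if (r[2]) "high" else if (r[4]) "low" else NA_character_
  if (!is.na(a_spot) && !is.na(b_spot)) {
    if (a_spot == b_spot) return(tie_out) # same spot, same step
    win_a <- a_spot                       # each reached its own spot
  } else if (!is.na(a_spot)) {
    spot <- if (a_spot == "high") spot_high else spot_low
    if (sqrt(sum((res$pose_b[1:2] - spot)^2)) <= arena$tie_radius)
      return(tie_out)
    win_a <- a_spot
  } else {
    spot <- if (b_spot == "high") spot_high else spot_low
    if (sqrt(sum((res$pose_a[1:2] - spot)^2)) <= arena$tie_radius)
      return(tie_out)
    win_a <- if (b_spot == "high") "low" else "high"
  }
  list(state_a = win_a,
       state_b = if (win_a == "high") "low" else "high",
       reward_a = if (win_a == "high") payoff$a else payoff$b,
       reward_b = if (win_a == "high") payoff$b else payoff$a,
       tie = FALSE)
}

#' Simulate one dyad through a full condition
#'
#' Creates two fresh learners and plays every round of the condition,
#' applying one actor-critic update per agent per round from its own
#' `(s_prev, a, r, s_t)` transition (the first round's previous state is
#' `tie`, the neutral label). Fully reproducible from `(condition, seed)`:
#' the seed drives action sampling, spot allocation, motor noise and the
#' `none` coin through one stream, and the caller's RNG state is left
#' untouched.
#'
#' @param condition A [game_condition()].
#' @param seed Integer seed for this dyad.
#' @param arena An [arena_config()] (dynamic mode only).
#' @param lcfg A [learning_config()].
#' @param f Forward speed constant of the reactive layer.
#' @param dyad_id Identifier written into the log.
#' @return A tibble with one row per round and columns `dyad_id,
#'   condition, mode, payoff_a, payoff_b, ablation, seed, round, action_a,
#'   action_b, state_a, state_b, reward_a, reward_b, tie, steps, none_a,
#'   none_b`. The final agents are attached as attribute `"agents"`.
#' @export
#' @examples
#' log <- play_dyad(game_condition("ballistic", "high", rounds = 10), seed = 1)
#' log
play_dyad <- function(condition, seed, arena = arena_config(),
                      lcfg = learning_config(), f = 0.3, dyad_id = 1L) {
  stopifnot(inherits(condition, "crl_condition"))
  n <- condition$rounds
  pay <- condition$payoff
  abl <- condition$ablation
  ballistic_round <- condition$mode == "ballistic" || abl == "adaptive_only"
  learning <- abl != "reactive_only"

  action_a <- action_b <- state_a <- state_b <- character(n)
  reward_a <- reward_b <- numeric(n)
  tie <- logical(n)
  steps <- integer(n)

  agents <- withr::with_seed(seed, {
    ag_a <- new_agent(lcfg)
    ag_b <- new_agent(lcfg)
    s_prev_a <- s_prev_b <- "tie"
    for (t in seq_len(n)) {
      if (learning) {
        aa <- select_action(ag_a, s_prev_a)
        ab <- select_action(ag_b, s_prev_b)
      } else {
        aa <- ab <- "none"
      }
      out <- if (ballistic_round) play_round_ballistic(aa, ab, pay)
             else play_round_dynamic(aa, ab, pay, arena, f, abl)
      action_a[t] <- aa;            action_b[t] <- ab
      state_a[t] <- out$state_a;    state_b[t] <- out$state_b
      reward_a[t] <- out$reward_a;  reward_b[t] <- out$reward_b
      tie[t] <- out$tie;            steps[t] <- out$steps
      if (learning) {
        ag_a <- agent_learn(ag_a, s_prev_a, aa, out$reward_a, out$state_a)
        ag_b <- agent_learn(ag_b, s_prev_b, ab, out$reward_b, out$state_b)
      }
      s_prev_a <- out$state_a
      s_prev_b <- out$state_b
    }
    list(a = ag_a, b = ag_b)
  })

  cond_label <- condition$label
  cond_mode <- condition$mode
  log <- tibble::tibble(
    dyad_id = as.integer(dyad_id), condition = cond_label,
    mode = cond_mode, payoff_a = pay$a, payoff_b = pay$b,
    ablation = abl, seed = as.integer(seed), round = seq_len(n),
    action_a = action_a, action_b = action_b,
    state_a = state_a, state_b = state_b,
    reward_a = reward_a, reward_b = reward_b,
    tie = tie, steps = steps,
    none_a = action_a == "none", none_b = action_b == "none")
  attr(log, "agents") <- agents
  log
}

#' Write / read a round log as CSV with a JSON config sidecar
#'
#' The CSV holds one row per round in the fixed column order of
#' [play_dyad()]; the sidecar `<path>.json` records the configuration used
#' to produce it so a log directory is self-describing.
#'
#' @param log A round-log tibble.
#' @param path CSV path.
#' @param config Optional list serialized to the sidecar.
#' @return `path`, invisibly (`write_dyad_log`); the log tibble with the
#'   sidecar attached as attribute `"config"` (`read_dyad_log`).
#' @export
write_dyad_log <- function(log, path, config = NULL) {
  readr::write_csv(log, path)
  if (!is.null(config))
    jsonlite::write_json(config, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dyad_log
#' @export
read_dyad_log <- function(path) {
  log <- readr::read_csv(path, col_types = readr::cols(
    dyad_id = "i", condition = "c", mode = "c", payoff_a = "d",
    payoff_b = "d", ablation = "c", seed = "i", round = "i",
    action_a = "c", action_b = "c", state_a = "c", state_b = "c",
    reward_a = "d", reward_b = "d", tie = "l", steps = "i",
    none_a = "l", none_b = "l"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(log, "config") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  log
}
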