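#' Learning configuration of the adaptive layer
#'
#' Tabular actor-critic temporal-difference learner over the three outcome
#' states (`high`, `low`, `tie`) and three round-level actions (`go_high`,
#' `go_low`, `none`).
#'
#' @param gamma Discount factor (default 0.40).
#' @param eta Critic learning rate (default 0.15).
#' @param delta Actor learning rate (default 0.45).
#' @param k Number of actions (3; used by the Laplace rule).
#' @return An object of class `crl_learning` (named list).
#' @export
learning_config <- function(gamma = 0.40, eta = 0.15, delta = 0.45, k = 3L) {
  stopifnot(gamma >= 0, gamma <= 1, eta > 0, delta > 0, k >= 1)
  structure(list(gamma = gamma, eta = eta, delta = delta, k = as.integer(k)),
            class = "crl_learning")
}

#' Create a fresh actor-critic agent
#'
#' The critic `V` starts at zero for every state; the actor's count matrix
#' `C` (actions x states) starts at zero, which through the Laplace rule
#' makes the initial policy uniform over actions in every state.
#'
#' @param cfg A [learning_config()].
#' @return An object of class `crl_agent` with fields `V`, `C`, `cfg` and
#'   the update counter `n_updates`.
#' @export
#' @examples
#' ag <- new_agent()
#' policy_probs(ag$C)
new_agent <- function(cfg = learning_config()) {
  structure(list(
    V = setNames(numeric(3), crl_states()),
    C = matrix(0, 3, 3, dimnames = list(crl_actions(), crl_states())),
    cfg = cfg, n_updates = 0L
  ), class = "crl_agent")
}

#' Action probabilities from actor counts (Laplace's law of succession)
#'
#' `P(a | s) = (C[a, s] + 1) / (sum_a C[a, s] + k)`: a generalized
#' histogram in which every action counts as seen once before any
#' observation, so zero counts give the uniform distribution and no
#' probability is ever null. Columns always sum to one.
#'
#' @param C Non-negative actions x states count matrix.
#' @param k Number of actions (defaults to `nrow(C)`).
#' @return Matrix of probabilities with the same dimnames as `C`.
#' @export
policy_probs <- function(C, k = nrow(C)) {
  stopifnot(all(C >= 0), all(is.finite(C)))
  t(t(C + 1) / (colSums(C) + k))
}

#' Sample the round action from the current policy
#'
#' @param agent A `crl_agent`.
#' @param state The previous round's outcome state for this agent.
#' @return One of `"go_high"`, `"go_low"`, `"none"`.
#' @export
select_action <- function(agent, state) {
  state <- match.arg(state, crl_states())
  p <- policy_probs(agent$C, agent$cfg$k)[, state]
  if (abs(sum(p) - 1) > 1e-8)
    stop("internal error: unnormalized policy column", call. = FALSE)
  sample(crl_actions(), 1L, prob = p)
}

#' Temporal-difference error
#'
#' `e(s_prev) = r + gamma * V(s_t) - V(s_prev)`: how much better or worse
#' the round went than the critic predicted.
#'
#' @param r Reward collected this round.
#' @param V Named state-value vector.
#' @param s_t This round's outcome state.
#' @param s_prev The previous round's outcome state.
#' @param cfg A [learning_config()].
#' @return Scalar TD error.
#' @export
#' @examples
#' V <- c(high = 2, low = 0, tie = 1)
#' td_error(4, V, "high", "tie", learning_config()) # 4 + 0.4*2 - 1 = 3.8
td_error <- function(r, V, s_t, s_prev, cfg = learning_config()) {
  unname(r + cfg$gamma * V[[s_t]] - V[[s_prev]])
}

#' Critic update
#'
#' Moves only the previous state's value: `V(s_prev) <- V(s_prev) + eta * e`.
#'
#' @param agent A `crl_agent`.
#' @param s_prev State whose value is corrected.
#' @param e TD error.
#' @return The updated agent.
#' @export
update_critic <- function(agent, s_prev, e) {
  agent$V[[s_prev]] <- agent$V[[s_prev]] + agent$cfg$eta * e
  agent
}

#' Actor update
#'
#' Adds `delta * e` to the count of the executed action in the previous
#' state, keeping the count at its lower bound of zero. Probabilities are
#' always derived from the counts via [policy_probs()], so a count driven
#' to zero pulls that column back toward uniform.
#'
#' @param agent A `crl_agent`.
#' @param a Executed action.
#' @param s_prev State in which it was executed.
#' @param e TD error.
#' @return The updated agent.
#' @export
update_actor <- function(agent, a, s_prev, e) {
  agent$C[a, s_prev] <- max(0, agent$C[a, s_prev] + agent$cfg$delta * e)
  agent
}

#' One full learning step from a round's experience
#'
#' Computes the TD error from `(s_prev, a, r, s_t)` and applies the critic
#' and actor updates in that order (both use the error computed from the
#' pre-update critic).
#'
#' @param agent A `crl_agent`.
#' @param s_prev,a,r,s_t The transition: previous state, executed action,
#'   reward collected, new outcome state.
#' @return The updated agent.
#' @export
agent_learn <- function(agent, s_prev, a, r, s_t) {
  e <- td_error(r, agent$V, s_t, s_prev, agent$cfg)
  agent <- update_critic(agent, s_prev, e)
  agent <- update_actor(agent, a, s_prev, e)
  agent$n_updates <- agent$n_updates + 1L
  agent
}

#' @export
tidy.crl_agent <- function(x, ...) {
  p <- policy_probs(x$C, x$cfg$k)
  tibble::tibble(
    state = rep(crl_states(), each = length(crl_actions())),
    action = rep(crl_actions(), times = length(crl_states())),
    count = as.vector(x$C[, crl_states()]),
    prob = as.vector(p[, crl_states()]),
    state_value = rep(unname(x$V[crl_states()]),
                      each = length(crl_actions()))
  )
}

#' @export
glance.crl_agent <- function(x, ...) {
  tibble::tibble(gamma = x$cfg$gamma, eta = x$cfg$eta, delta = x$cfg$delta,
                 k = x$cfg$k, n_updates = x$n_updates,
                 mean_state_value = mean(x$V))
}

#' @export
print.crl_agent <- function(x, ...) {
  cat("<crl_agent> actor-critic TD learner,", x$n_updates, "updates\n")
  cat("V:", paste(sprintf("%s=%.3f", names(x$V), x$V), collapse = "  "), "\n")
  cat("P(a|s):\n")
  print(round(policy_probs(x$C, x$cfg$k), 3))
  invisible(x)
}
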