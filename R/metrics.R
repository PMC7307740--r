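#' Coordination metrics for a single dyad's round log
#'
#' `efficiency()` is the collective reward earned divided by the maximum
#' collectively attainable reward, `sum(reward_a + reward_b) / (rounds *
#' (a + b))`. Under the scoring rule (every non-tie round pays out exactly
#' `a + b`, every tie pays 0) this equals the fraction of non-tie rounds.
#'
#' `fairness()` is `1 - |n_a - n_b| / (n_a + n_b)` where `n_a`, `n_b`
#' count the rounds in which each agent took the high reward: 1 when the
#' high payoff was split evenly, 0 under complete dominance. Undefined
#' (NA, with a warning) for an all-tie log.
#'
#' `reliance_al()` is the fraction of agent-rounds in which a spot-choice
#' action (not `none`) was taken, i.e. how often behavior was steered by
#' the adaptive layer rather than left to the reactive layer alone.
#'
#' @param rounds A single dyad's rounds (tibble from [play_dyad()] or a
#'   compatible CSV).
#' @return A scalar.
#' @name dyad_metric
NULL

one_dyad <- function(rounds) {
  if (nrow(rounds) == 0)
    stop("metric undefined on an empty round log", call. = FALSE)
  if (length(unique(rounds$dyad_id)) > 1)
    stop("round log mixes dyads; use dyad_metrics()", call. = FALSE)
  invisible(rounds)
}

#' @rdname dyad_metric
#' @export
efficiency <- function(rounds) {
  one_dyad(rounds)
  total <- rounds$payoff_a[1] + rounds$payoff_b[1]
  sum(rounds$reward_a + rounds$reward_b) / (nrow(rounds) * total)
}

#' @rdname dyad_metric
#' @export
fairness <- function(rounds) {
  one_dyad(rounds)
  n_a <- sum(rounds$state_a == "high")
  n_b <- sum(rounds$state_b == "high")
  if (n_a + n_b == 0) {
    warning("fairness undefined: no non-tie rounds in this log",
            call. = FALSE)
    return(NA_real_)
  }
  1 - abs(n_a - n_b) / (n_a + n_b)
}

#' @rdname dyad_metric
#' @export
reliance_al <- function(rounds) {
  one_dyad(rounds)
  mean(c(rounds$action_a, rounds$action_b) != "none")
}

# Three-symbol outcome alphabet of a round, from the dyad's point of view.
outcome_symbol <- function(rounds) {
  ifelse(rounds$tie, "tie",
         ifelse(rounds$state_a == "high", "a_high", "b_high"))
}

#' Per-round surprisal of the outcome sequence
#'
#' Surprisal is the negative log probability of each round's outcome under
#' an empirical predictor fitted to the recent past: the probability of
#' outcome `o` at round `t` is estimated from the preceding
#' `min(window, t - 1)` rounds with add-one smoothing over the 3-symbol
#' alphabet `{a_high, b_high, tie}`, `p = (count + 1) / (m + 3)`. An empty
#' history therefore gives the uniform `-log2(1/3) = 1.585` bits. The
#' series drops as outcomes become predictable, i.e. as a convention
#' forms.
#'
#' @inheritParams dyad_metric
#' @param window Rounds of history used by the estimator (default 8).
#' @param smoothing Apply add-one smoothing (default TRUE; without it an
#'   unseen outcome has probability 0 and infinite surprisal).
#' @param log_base Base of the logarithm (default 2: bits).
#' @return `surprisal_series()`: numeric vector, one value per round.
#'   `stability()`: their mean; lower means a more stable, more
#'   predictable interaction.
#' @export
surprisal_series <- function(rounds, window = 8, smoothing = TRUE,
                             log_base = 2) {
  one_dyad(rounds)
  stopifnot(window >= 1)
  sym <- outcome_symbol(rounds)
  n <- length(sym)
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window)
    hist <- if (t == 1L) character(0) else sym[lo:(t - 1L)]
    m <- length(hist)
    cnt <- sum(hist == sym[t])
    p <- if (smoothing) (cnt + 1) / (m + 3) else cnt / m
    out[t] <- -log(p, base = log_base)
  }
  out
}

#' @rdname surprisal_series
#' @export
stability <- function(rounds, window = 8, smoothing = TRUE, log_base = 2) {
  mean(surprisal_series(rounds, window, smoothing, log_base))
}

#' Classify the convention a dyad settled into
#'
#' Looks at the last `tail` non-tie rounds: `"dominance"` if one agent
#' took the high reward in at least 90% of them, `"turn_taking"` if the
#' high-reward winner strictly alternates in at least 90% of consecutive
#' pairs, otherwise `"none"`. Fewer than 4 non-tie rounds in the tail is
#' `"none"`. The thresholds are reporting conveniences for labeling
#' equilibria, not part of the learning model.
#'
#' @inheritParams dyad_metric
#' @param tail Number of trailing non-tie rounds examined (default 20).
#' @return `"turn_taking"`, `"dominance"` or `"none"`.
#' @export
classify_convention <- function(rounds, tail = 20) {
  one_dyad(rounds)
  stopifnot(tail <= max(nrow(rounds), tail))
  winners <- ifelse(rounds$state_a[!rounds$tie] == "high", "a", "b")
  winners <- utils::tail(winners, tail)
  if (length(winners) < 4) return("none")
  share <- max(mean(winners == "a"), mean(winners == "b"))
  if (share >= 0.9) return("dominance")
  alt <- mean(winners[-1] != winners[-length(winners)])
  if (alt >= 0.9) return("turn_taking")
  "none"
}

#' Per-dyad metric table for a multi-dyad log
#'
#' Splits a round log by dyad and computes every coordination metric,
#' returning one row per dyad. Dyads without any non-tie round get
#' `fairness = NA` (they are dropped, with a message, when aggregating).
#'
#' @param log Round-log tibble covering one or more dyads/conditions.
#' @param window,smoothing,log_base Passed to [stability()].
#' @param tail Passed to [classify_convention()].
#' @return Tibble with columns `condition, mode, payoff_a, payoff_b,
#'   ablation, dyad_id, seed, rounds, efficiency, fairness, stability,
#'   reliance_al, convention`.
#' @export
#' @examples
#' log <- play_dyad(game_condition("ballistic", "high", rounds = 20), seed = 2)
#' dyad_metrics(log)
dyad_metrics <- function(log, window = 8, smoothing = TRUE, log_base = 2,
                         tail = 20) {
  if (nrow(log) == 0) {
    warning("empty round log: no metrics to compute", call. = FALSE)
    return(tibble::tibble())
  }
  log |>
    dplyr::group_by(.data$condition, .data$mode, .data$payoff_a,
                    .data$payoff_b, .data$ablation, .data$dyad_id,
                    .data$seed) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      tibble::tibble(
        condition = d$condition[1], mode = d$mode[1],
        payoff_a = d$payoff_a[1], payoff_b = d$payoff_b[1],
        ablation = d$ablation[1], dyad_id = d$dyad_id[1],
        seed = d$seed[1], rounds = nrow(d),
        efficiency = efficiency(d),
        fairness = suppressWarnings(fairness(d)),
        stability = stability(d, window, smoothing, log_base),
        reliance_al = reliance_al(d),
        convention = classify_convention(d, tail))
    }) |>
    dplyr::bind_rows()
}

#' Aggregate per-dyad metrics into condition means and standard errors
#'
#' @param metrics Output of [dyad_metrics()].
#' @return Long tibble with one row per condition and metric: `mean`,
#'   `se` (standard error across dyads) and `n` (dyads contributing;
#'   all-tie dyads do not contribute to fairness).
#' @export
condition_summary <- function(metrics) {
  n_na <- sum(is.na(metrics$fairness))
  if (n_na > 0)
    message(n_na, " all-tie dyad(s) excluded from fairness aggregation")
  metrics |>
    tidyr::pivot_longer(c("efficiency", "fairness", "stability",
                          "reliance_al"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$condition, .data$mode, .data$payoff_a,
                    .data$payoff_b, .data$ablation, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop")
}
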