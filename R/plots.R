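#' Bar chart of condition means with standard-error bars
#'
#' One facet per metric, one bar per condition, error bars showing the
#' standard error across dyads — the standard way of presenting the
#' efficiency / fairness / stability profile of an experiment.
#'
#' @param summary Output of [condition_summary()] (or the `summary`
#'   element of a [run_grid()] result).
#' @param metrics Which metrics to show.
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summary,
                                   metrics = c("efficiency", "fairness",
                                               "stability")) {
  d <- dplyr::filter(summary, .data$metric %in% metrics)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$mean,
                                  fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean across dyads", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.crl_experiment <- function(object, ...) {
  plot_condition_summary(object$summary, ...)
}

#' Per-round surprisal trace of one dyad
#'
#' Shows how predictable the dyad's outcomes become over the rounds; the
#' trace falls once a convention (turn taking or dominance) forms and
#' shoots up whenever it breaks.
#'
#' @param rounds One dyad's round log.
#' @param window,smoothing,log_base Passed to [surprisal_series()].
#' @return A ggplot object.
#' @export
plot_surprisal <- function(rounds, window = 8, smoothing = TRUE,
                           log_base = 2) {
  d <- tibble::tibble(
    round = rounds$round,
    surprisal = surprisal_series(rounds, window, smoothing, log_base),
    outcome = outcome_symbol(rounds))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$round, y = .data$surprisal)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$outcome), size = 1.6) +
    ggplot2::labs(y = "surprisal (bits)", color = "outcome") +
    ggplot2::theme_minimal()
}

#' Reliance on the adaptive layer across the payoff sweep
#'
#' @param sweep Output of [run_payoff_sweep()].
#' @return A ggplot object.
#' @export
plot_reliance_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data$ratio),
                                      y = .data$mean_reliance,
                                      group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_reliance - .data$se,
      ymax = .data$mean_reliance + .data$se)) +
    ggplot2::geom_hline(yintercept = 2 / 3, linetype = "dashed") +
    ggplot2::labs(x = "high : low payoff", y = "reliance on adaptive layer") +
    ggplot2::theme_minimal()
}

#' Trajectories of one dynamic round
#'
#' @param round_result Result of [play_round_dynamic()] called with
#'   `record = TRUE`.
#' @param arena The [arena_config()] used.
#' @return A ggplot object.
#' @export
plot_round_trajectory <- function(round_result, arena = arena_config()) {
  traj <- round_result$trajectory
  if (is.null(traj)) stop("round was not recorded; use record = TRUE",
                          call. = FALSE)
  d <- dplyr::bind_rows(
    tibble::tibble(agent = "a", x = traj[, "xa"], y = traj[, "ya"]),
    tibble::tibble(agent = "b", x = traj[, "xb"], y = traj[, "yb"]))
  spots <- tibble::tibble(
    x = vapply(arena$spot_positions, `[`, numeric(1), 1),
    y = vapply(arena$spot_positions, `[`, numeric(1), 2))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, color = .data$agent)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = spots, inherit.aes = FALSE,
                        ggplot2::aes(.data$x, .data$y), shape = 21,
                        size = 8, fill = "palegreen3") +
    ggplot2::coord_fixed(xlim = c(0, arena$width),
                         ylim = c(0, arena$height)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
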