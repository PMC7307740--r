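#' Plan a set of conditions to simulate
#'
#' @param conditions Named list of [game_condition()] objects (names become
#'   condition labels if the conditions carry none).
#' @param dyads Dyads per condition.
#' @param seed Master seed; every dyad gets an independent seed derived
#'   from it, so individual dyads are reproducible regardless of execution
#'   order.
#' @param arena,lcfg,f Shared simulation configuration.
#' @return An object of class `crl_plan`.
#' @export
experiment_plan <- function(conditions, dyads = 50, seed = 1,
                            arena = arena_config(),
                            lcfg = learning_config(), f = 0.3) {
  stopifnot(length(conditions) >= 1, dyads >= 1)
  labels <- vapply(conditions, function(x) x$label, character(1))
  if (anyDuplicated(labels))
    stop("conditions must be distinct", call. = FALSE)
  structure(list(conditions = conditions, dyads = as.integer(dyads),
                 seed = as.integer(seed), arena = arena, lcfg = lcfg,
                 f = f),
            class = "crl_plan")
}

#' The default 2x2 condition grid
#'
#' Ballistic/dynamic crossed with high (4 vs 1, 50 rounds) and low (2 vs 1,
#' 60 rounds) payoffs.
#'
#' @inheritParams experiment_plan
#' @return A `crl_plan` with four conditions.
#' @export
default_grid_plan <- function(dyads = 50, seed = 1, ...) {
  experiment_plan(list(
    game_condition("ballistic", "high"),
    game_condition("ballistic", "low"),
    game_condition("dynamic", "high"),
    game_condition("dynamic", "low")), dyads = dyads, seed = seed, ...)
}

# One seed per dyad per condition, derived from the master seed.
draw_dyad_seeds <- function(master, n_conditions, dyads) {
  withr::with_seed(master, {
    matrix(sample.int(.Machine$integer.max, n_conditions * dyads),
           nrow = dyads)
  })
}

#' Run every dyad of a plan and aggregate the metrics
#'
#' Simulates `dyads` independent dyads for each condition of the plan,
#' computes per-dyad coordination metrics and the per-condition mean and
#' standard error. Optionally persists the round log, the per-dyad metric
#' table and the summary as CSV under `out_dir`.
#'
#' @param plan A [experiment_plan()].
#' @param out_dir Optional output directory.
#' @return An object of class `crl_experiment`: list with `log` (all
#'   rounds), `dyads` (per-dyad metrics), `summary` (condition means with
#'   standard errors) and `plan`.
#' @export
#' @examples
#' plan <- experiment_plan(list(game_condition("ballistic", "high",
#'                                             rounds = 15)),
#'                         dyads = 4, seed = 7)
#' run_grid(plan)$summary
run_grid <- function(plan, out_dir = NULL) {
  stopifnot(inherits(plan, "crl_plan"))
  seeds <- draw_dyad_seeds(plan$seed, length(plan$conditions), plan$dyads)
  log <- purrr::imap(plan$conditions, function(cond, i) {
    idx <- if (is.character(i)) match(i, names(plan$conditions)) else i
    purrr::map(seq_len(plan$dyads), function(d) {
      tryCatch(
        play_dyad(cond, seed = seeds[d, idx], arena = plan$arena,
                  lcfg = plan$lcfg, f = plan$f, dyad_id = d),
        error = function(e) stop("dyad ", d, " (seed ", seeds[d, idx],
                                 ", condition ", cond$label, ") failed: ",
                                 conditionMessage(e), call. = FALSE))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  if (nrow(log) == 0) {
    warning("plan produced no rounds; metrics are empty", call. = FALSE)
    res <- list(log = log, dyads = tibble::tibble(),
                summary = tibble::tibble(), plan = plan)
    return(structure(res, class = "crl_experiment"))
  }
  dyads <- dyad_metrics(log)
  res <- list(log = log, dyads = dyads,
              summary = condition_summary(dyads), plan = plan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dyad_log(log, file.path(out_dir, "rounds.csv"),
                   config = list(seed = plan$seed, dyads = plan$dyads,
                                 conditions = names(plan$conditions)))
    readr::write_csv(dyads, file.path(out_dir, "dyad_metrics.csv"))
    readr::write_csv(res$summary, file.path(out_dir, "summary.csv"))
  }
  structure(res, class = "crl_experiment")
}

#' @export
print.crl_experiment <- function(x, ...) {
  cat("<crl_experiment>", length(x$plan$conditions), "condition(s),",
      x$plan$dyads, "dyads each, master seed", x$plan$seed, "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Layer-ablation study
#'
#' Runs the full architecture against its two ablations in dynamic mode:
#' `reactive_only` disables the adaptive layer entirely (every action is
#' logged as `none`, so reliance on the adaptive layer is 0 by
#' construction) and `adaptive_only` removes the reactive layer, resolving
#' rounds exactly as in ballistic mode.
#'
#' @param payoffs Character vector of payoff presets to cross with the
#'   ablations.
#' @param ablations Which model variants to run.
#' @inheritParams experiment_plan
#' @param out_dir Optional output directory.
#' @return A `crl_experiment` (one condition per ablation x payoff).
#' @export
run_ablations <- function(payoffs = c("high", "low"),
                          ablations = c("full", "reactive_only",
                                        "adaptive_only"),
                          dyads = 50, seed = 1, ...) {
  conds <- purrr::map(ablations, function(ab) {
    purrr::map(payoffs, function(p)
      game_condition("dynamic", p, ablation = ab))
  }) |> purrr::list_flatten()
  run_grid(experiment_plan(conds, dyads = dyads, seed = seed, ...))
}

#' Payoff sweep: reliance on the adaptive layer vs payoff contrast
#'
#' Simulates dynamic-mode dyads for a series of payoff schemes with an
#' increasing high/low contrast (default 1-1 through 32-1) and reports the
#' mean fraction of agent-rounds steered by the adaptive layer (actions
#' other than `none`). Before any learning that fraction is 2/3 (three
#' equiprobable actions, one of which is `none`).
#'
#' @param ratios High-spot payoffs swept against a low spot fixed at 1.
#' @param dyads Dyads per payoff scheme.
#' @param rounds Rounds per dyad.
#' @param seed Master seed.
#' @inheritParams experiment_plan
#' @return Tibble with one row per scheme: `ratio`, `mean_reliance`, `se`,
#'   `n`, plus the per-dyad table as attribute `"dyads"`.
#' @export
run_payoff_sweep <- function(ratios = c(1, 2, 4, 8, 16, 32), dyads = 50,
                             rounds = 50, seed = 1, ...) {
  stopifnot(!is.unsorted(ratios))
  conds <- purrr::map(ratios, function(r)
    game_condition("dynamic", payoff_scheme(r, 1), rounds = rounds))
  exp <- run_grid(experiment_plan(conds, dyads = dyads, seed = seed, ...))
  out <- exp$dyads |>
    dplyr::group_by(ratio = .data$payoff_a) |>
    dplyr::summarise(mean_reliance = mean(.data$reliance_al),
                     se = stats::sd(.data$reliance_al) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$ratio)
  attr(out, "dyads") <- exp$dyads
  out
}

#' Condition-comparison statistics for the coordination metrics
#'
#' For each metric, screens every condition group for normality
#' (Shapiro-Wilk at the 0.05 level); if all groups look Gaussian the
#' omnibus test is a one-way ANOVA followed by pairwise Welch t-tests,
#' otherwise a Kruskal-Wallis H-test followed by pairwise Mann-Whitney
#' U-tests. Pairwise p-values are Holm-adjusted. Groups smaller than 3 are
#' skipped with a notice.
#'
#' @param metrics Per-dyad metric table from [dyad_metrics()] (at least
#'   two conditions).
#' @param which Metric columns to test.
#' @return An object of class `crl_stats`: tibble with one row per metric
#'   (`normal`, `test`, `statistic`, `df`, `p_value`) and a list-column
#'   `pairwise` of pairwise-comparison tibbles. [tidy()] unnests the
#'   pairwise table, [glance()] returns the omnibus rows.
#' @export
run_stats <- function(metrics, which = c("efficiency", "fairness",
                                         "stability")) {
  conds <- unique(metrics$condition)
  stopifnot(length(conds) >= 2)
  rows <- purrr::map(which, function(m) {
    d <- metrics[!is.na(metrics[[m]]), c("condition", m)]
    names(d) <- c("condition", "value")
    sizes <- table(d$condition)
    if (any(sizes < 3)) {
      message("skipping ", m, ": group(s) with fewer than 3 dyads")
      return(tibble::tibble(metric = m, normal = NA, test = "skipped",
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, pairwise = list(NULL)))
    }
    # constant groups break shapiro.test; a constant group is non-Gaussian
    grps <- split(d$value, d$condition)
    normal <- all(vapply(grps, function(v) {
      if (length(unique(v)) == 1) return(FALSE)
      stats::shapiro.test(v)$p.value > 0.05
    }, logical(1)))
    if (normal) {
      fit <- stats::aov(value ~ condition, data = d)
      s <- summary(fit)[[1]]
      pw <- stats::pairwise.t.test(d$value, d$condition, pool.sd = FALSE,
                                   p.adjust.method = "holm")
      omn <- tibble::tibble(metric = m, normal = TRUE, test = "anova",
                            statistic = s[["F value"]][1],
                            df = s[["Df"]][1], p_value = s[["Pr(>F)"]][1])
    } else {
      kw <- stats::kruskal.test(d$value, factor(d$condition))
      pw <- stats::pairwise.wilcox.test(d$value, d$condition,
                                        p.adjust.method = "holm",
                                        exact = FALSE)
      omn <- tibble::tibble(metric = m, normal = FALSE,
                            test = "kruskal-wallis",
                            statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value)
    }
    ptab <- as.data.frame(as.table(pw$p.value)) |>
      stats::setNames(c("group1", "group2", "p_value")) |>
      dplyr::filter(!is.na(.data$p_value)) |>
      tibble::as_tibble()
    omn$pairwise <- list(ptab)
    omn
  })
  structure(dplyr::bind_rows(rows), class = c("crl_stats",
                                              class(tibble::tibble())))
}

#' @export
tidy.crl_stats <- function(x, ...) {
  x |>
    dplyr::select("metric", "test", "pairwise") |>
    tidyr::unnest("pairwise")
}

#' @export
glance.crl_stats <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"pairwise")
}
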