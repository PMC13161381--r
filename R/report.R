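# Tidy accessors, plots and structured logs for fitted runs.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-episode tidy log of a fitted run
#'
#' @param x A `ward_fit`.
#' @param ... Unused.
#' @return The per-episode log tibble (episode, return, falls, lambda_mean,
#'   branch fractions, epsilon), with seed and mode columns attached.
#' @export
tidy.ward_fit <- function(x, ...) {
  dplyr::mutate(x$log, seed = x$seed, mode = x$mode)
}

#' One-row summary of a fitted run
#'
#' Computes the headline metrics of a run against the configuration's
#' optimal episode return: mean return, regret rate over all episodes,
#' convergence percentage over the final band (episodes 201 onward when the
#' run is long enough, otherwise the final 60%), total falls, pathway-usage
#' fractions, and the first step count at which a 20-episode moving average
#' of normalised return reaches 90%.
#'
#' @param x A `ward_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.ward_fit <- function(x, ...) {
  g <- episode_gstar(x$config)
  n <- nrow(x$log)
  band <- if (n >= 500L) 201:n else max(1L, floor(0.4 * n) + 1L):n
  se <- sample_efficiency(x$log$return, x$log$return, g,
                          steps_per_episode = x$config$steps_per_episode)
  tibble::tibble(
    mode = x$mode, seed = x$seed, episodes = n, gstar = g,
    mean_return = mean(x$log$return),
    regret_pct = regret_rate(x$log$return, g),
    convergence_pct = convergence_pct(x$log$return, g, band),
    falls = as.integer(sum(x$log$falls)),
    lambda_mean = mean(x$log$lambda_mean),
    mb_frac = mean(x$log$mb_frac),
    reflex_frac = mean(x$log$reflex_frac),
    samples_to_90 = se$samples_a
  )
}

#' Full metrics report for a fitted run
#'
#' Bundles the one-row summary, the per-episode log, the lambda trace
#' summary and the convergence-by-band table (training bands 1-50, 51-100,
#' 101-200, 201-end). Every number is recomputable from the per-episode and
#' per-step logs.
#'
#' @param fit A `ward_fit`.
#' @return A `metrics_report` list with `summary`, `bands`, `episodes`.
#' @export
metrics_report <- function(fit) {
  g <- episode_gstar(fit$config)
  n <- nrow(fit$log)
  cuts <- list(`1-50` = 1:min(50L, n),
               `51-100` = if (n >= 51L) 51:min(100L, n),
               `101-200` = if (n >= 101L) 101:min(200L, n),
               `201-end` = if (n >= 201L) 201:n)
  cuts <- cuts[!vapply(cuts, is.null, logical(1))]
  bands <- tibble::tibble(
    band = names(cuts),
    convergence_pct = vapply(cuts, function(b) {
      convergence_pct(fit$log$return, g, b)
    }, numeric(1)))
  structure(list(summary = glance(fit), bands = bands,
                 episodes = tidy(fit)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  print(as.data.frame(x$bands), row.names = FALSE)
  invisible(x)
}

#' Learning-curve and diagnostics plots for a fitted run
#'
#' @param object A `ward_fit`.
#' @param what `"return"` (per-episode return with the optimal-return
#'   reference line), `"lambda"` (arbitration trace), or `"falls"`
#'   (cumulative falls).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ward_fit <- function(object, what = c("return", "lambda", "falls"),
                              ...) {
  what <- match.arg(what)
  log <- object$log
  if (what == "return") {
    g <- episode_gstar(object$config)
    ggplot2::ggplot(log, ggplot2::aes(x = .data$episode, y = .data$return)) +
      ggplot2::geom_line(colour = "grey40") +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                           colour = "steelblue", span = 0.3) +
      ggplot2::geom_hline(yintercept = g, linetype = 2, colour = "firebrick") +
      ggplot2::labs(x = "episode", y = "episode return",
                    title = sprintf("Learning curve (%s), G* = %.1f",
                                    object$mode, g))
  } else if (what == "lambda") {
    ggplot2::ggplot(log, ggplot2::aes(x = .data$episode,
                                      y = .data$lambda_mean)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_hline(yintercept = 0.7, linetype = 2) +
      ggplot2::labs(x = "episode", y = "mean lambda",
                    title = "Meta-controller arbitration trace")
  } else {
    log$cum_falls <- cumsum(log$falls)
    ggplot2::ggplot(log, ggplot2::aes(x = .data$episode,
                                      y = .data$cum_falls)) +
      ggplot2::geom_step(colour = "firebrick") +
      ggplot2::labs(x = "episode", y = "cumulative falls",
                    title = "Fall events")
  }
}

#' Write a per-step JSONL episode log
#'
#' One JSON record per step: episode, step, patient id, discrete state
#' index, action, reward, lambda, branch, and the step's event labels.
#' Requires a fit trained with `log_steps = TRUE`.
#'
#' @param fit A `ward_fit` with a step log.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_episode_log <- function(fit, path) {
  if (is.null(fit$step_log)) {
    stop("write_episode_log: fit has no step log (train with log_steps = TRUE)",
         call. = FALSE)
  }
  branch_names <- c("MB", "MF", "reflex")
  con <- file(path, "w")
  on.exit(close(con))
  sl <- fit$step_log
  for (i in seq_len(nrow(sl))) {
    ev <- c(if (isTRUE(sl$fall[i] > 0)) "fall",
            if (sl$branch[i] == 3) "reflex_override")
    rec <- list(episode = sl$episode[i], step = sl$step[i],
                patient_id = 1L, state_index = sl$state[i],
                action = ward_actions()[sl$action[i]],
                reward = sl$reward[i], lambda = sl$lambda[i],
                branch = branch_names[sl$branch[i]],
                events = as.list(ev))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write the per-run summary CSV
#'
#' Columns: episode, return, regret_pct (per-episode normalised shortfall,
#' clipped at 0), falls, mb_fraction.
#'
#' @param fit A `ward_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_summary <- function(fit, path) {
  g <- episode_gstar(fit$config)
  out <- tibble::tibble(
    episode = fit$log$episode,
    return = fit$log$return,
    regret_pct = pmax(0, 100 * (g - fit$log$return) / g),
    falls = fit$log$falls,
    mb_fraction = fit$log$mb_frac)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Desk-scale composite scorecard for the hybrid agent
#'
#' Computes the seven combined-reward components from short paired runs:
#' transferability and generalization as band convergence on perturbed
#' environment variants (shifted event rates), robustness under the
#' noise-plus-delay protocol, sample efficiency versus the DQN-lite
#' baseline, exploration-exploitation as `100 - regret`, sensitivity as
#' `100 - max sweep deviation`, and interpretability as the fraction of
#' steps with complete diagnostics. Scores are clipped into `[0, 100]`
#' before weighting.
#'
#' @param config A [ward_config()].
#' @param agent A [hybrid_config()].
#' @param seeds Seeds for each run.
#' @param episodes Episodes per run (scorecards are usually run short).
#' @return A [scorecard()] result.
#' @export
compute_scorecard <- function(config, agent = hybrid_config(),
                              seeds = config$seed,
                              episodes = config$episodes) {
  conv <- function(cfg) {
    mean(vapply(seeds, function(sd) {
      f <- run_care_loop(cfg, agent, sd, "hybrid", episodes)
      n <- nrow(f$log)
      convergence_pct(f$log$return, episode_gstar(cfg),
                      max(1L, floor(0.4 * n) + 1L):n)
    }, numeric(1)))
  }
  base <- conv(config)
  transfer_cfg <- ward_config_modify(config, rate_fever = config$rate_fever * 2,
                                     rate_distress = config$rate_distress * 1.5)
  general_cfg <- ward_config_modify(config, rate_motor_failure = 0.01)
  robust_cfg <- ward_config_modify(config, sensor_noise_pct = 0.08,
                                   observation_delay_steps = 1L)
  fit_h <- run_care_loop(config, agent, seeds[1], "hybrid", episodes)
  fit_d <- train_dqn_lite(config, seed = seeds[1], episodes = episodes,
                          agent = agent)
  g <- episode_gstar(config)
  se <- sample_efficiency(fit_h$log$return, fit_d$log$return, g,
                          threshold_fraction = 0.9,
                          steps_per_episode = config$steps_per_episode)
  sweep <- sensitivity_sweep(config, list(alpha0 = c(0.05, 0.1)),
                             agent = agent, seeds = seeds[1],
                             episodes = max(10L, episodes %/% 2L))
  fit_diag <- run_care_loop(config, agent, seeds[1], "hybrid",
                            min(episodes, 20L), log_steps = TRUE)
  interp <- 100 * mean(stats::complete.cases(
    fit_diag$step_log[, c("lambda", "branch", "q_mb", "q_mf", "hybrid")]))
  clip <- function(x) min(100, max(0, x))
  components <- c(
    transferability = clip(conv(transfer_cfg)),
    robustness = clip(conv(robust_cfg)),
    generalization = clip(conv(general_cfg)),
    sample_efficiency = clip(if (is.na(se$percent)) 0 else se$percent + 50),
    exploration_exploitation = clip(100 - regret_rate(fit_h$log$return, g)),
    sensitivity = clip(100 - max(abs(sweep$deviation_pct))),
    interpretability = clip(interp))
  scorecard(components)
}

# modify a validated config, re-validating
ward_config_modify <- function(cfg, ...) {
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  validate_ward_config(cfg)
  cfg
}
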