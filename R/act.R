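# Single-decision interface: the full acting pipeline over a cognitive
# chart, reusable outside the training loop (e.g. driving the multi-patient
# ward simulator with a shared, parameter-sharing agent).

#' Create a hybrid agent
#'
#' Bundles the learnable state of the hybrid decision-maker: the model-free
#' Q table, the cached model-based value table, the empirical transition
#' model, visit counts, the meta-controller and the incumbent action.
#' Tables are sized to the packaged discrete state space.
#'
#' @param agent_config A [hybrid_config()].
#' @param max_safe_angle Safe-tilt threshold used by reflex and rules.
#' @return A `hybrid_agent` object.
#' @export
hybrid_agent <- function(agent_config = hybrid_config(),
                         max_safe_angle = 25) {
  structure(list(
    cfg = agent_config,
    q_mf = q_table(N_OBS, N_ACT, initial = agent_config$q_init),
    q_mb = q_table(N_OBS, N_ACT, initial = agent_config$q_init),
    model = transition_model(N_OBS, N_ACT),
    mc = meta_controller(tau = agent_config$tau,
                         lambda_trigger = agent_config$lambda_trigger),
    max_safe_angle = max_safe_angle,
    prev_action = 1L,
    steps = 0L
  ), class = "hybrid_agent")
}

#' One decision of the hybrid pipeline
#'
#' Runs the fixed acting order on a cognitive chart: safety reflex, then
#' symbolic rules (force/mask), then meta-controller lambda, then
#' arbitration into the model-based branch (with a counterfactual scan when
#' lambda exceeds the trigger) or the epsilon-greedy model-free branch. The
#' model-based branch is additionally forced when the chart shows distress
#' (emotional score above its trigger) or any body-sensor anomaly. Full
#' diagnostics are always returned: lambda is computed and logged even when
#' the reflex preempts the learned policy.
#'
#' @param agent A [hybrid_agent()].
#' @param chart A [build_chart()] observation.
#' @param rules Symbolic rule set (tibble as from [clinical_rules()]).
#' @param motor_failure Hardware-level motor-failure flag sensed by the
#'   reflex (not part of the observed chart).
#' @param epsilon Exploration rate of the model-free branch.
#' @return List with `action` (name), `diagnostics` (lambda, branch,
#'   advantages, fired rule ids, state index).
#' @export
act <- function(agent, chart, rules = clinical_rules(agent$max_safe_angle),
                motor_failure = FALSE, epsilon = 0.05) {
  ds <- discretize(chart, agent$max_safe_angle)
  s <- ds$index
  q_mb_row <- agent$q_mb$values[s, ]
  q_mf_row <- agent$q_mf$values[s, ]
  lambda <- if (agent$cfg$ablate_meta) agent$cfg$fixed_lambda else
    meta_lambda(q_mb_row, q_mf_row, agent$cfg$tau)

  tilt_unsafe <- chart$P_states$tilt_angle > agent$max_safe_angle
  reflex <- if (isTRUE(agent$cfg$reflex)) {
    safety_reflex(tilt_unsafe, motor_failure)
  }
  scan <- NULL
  fired <- character()
  if (!is.null(reflex)) {
    action <- reflex
    branch <- "reflex"
  } else {
    allowed <- ward_actions()
    forced <- NULL
    if (!agent$cfg$ablate_rules) {
      ra <- apply_rules(rules, chart, allowed)
      allowed <- ra$allowed_actions
      forced <- ra$forced_action
      fired <- ra$fired
    }
    anomaly <- ds$bin_vector[["hr"]] != 2L || ds$bin_vector[["bp"]] != 2L ||
      ds$bin_vector[["spo2"]] == 1L || ds$bin_vector[["temp"]] == 2L
    distress <- ds$bin_vector[["distress"]] == 2L
    branch <- if (distress || anomaly) "MB" else arbitrate(lambda)
    if (!is.null(forced)) {
      action <- forced
    } else if (stats::runif(1) < epsilon) {
      # exploratory draws bypass both branches (epsilon-greedy combined
      # with the confidence arbitration)
      action <- allowed[sample.int(length(allowed), 1L)]
    } else if (branch == "MB") {
      allowed_ids <- match(allowed, ward_actions())
      if (!agent$cfg$ablate_counterfactual &&
          lambda > agent$cfg$lambda_trigger) {
        scan <- counterfactual_scan(
          agent$model, s, incumbent = agent$prev_action,
          actions = allowed_ids, gamma = agent$cfg$gamma,
          threshold = agent$cfg$cf_threshold,
          depth = agent$cfg$planning_depth,
          visits = agent$q_mf$visits[s, allowed_ids],
          bonus = agent$cfg$cf_bonus,
          q_mb = q_mb_row)
        action <- if (isTRUE(attr(scan, "prioritized"))) {
          ward_actions()[scan$action[1L]]
        } else {
          allowed[which.max(q_mb_row[allowed_ids])]
        }
      } else {
        action <- allowed[which.max(q_mb_row[allowed_ids])]
      }
    } else {
      allowed_ids <- match(allowed, ward_actions())
      action <- ward_actions()[mf_select(agent$q_mf, s, epsilon, allowed_ids)]
    }
  }
  list(action = action,
       diagnostics = list(lambda = lambda, branch = branch,
                          state_index = s, advantages = scan,
                          fired_rules = fired,
                          hybrid_value = hybrid_q(
                            lambda, q_mb_row[match(action, ward_actions())],
                            q_mf_row[match(action, ward_actions())])))
}

#' Record an experienced transition into a hybrid agent
#'
#' Applies the model-free backup (Robbins-Monro learning-rate schedule) and
#' the transition-model count update, advances the incumbent action, and
#' periodically refreshes the cached model-based values by planning sweeps.
#'
#' @param agent A [hybrid_agent()].
#' @param s,action,r,s_next Transition: state index, action name or id,
#'   reward, successor state index.
#' @return The updated agent.
#' @export
observe <- function(agent, s, action, r, s_next) {
  a <- if (is.character(action)) match(action, ward_actions()) else
    as.integer(action)
  alpha <- agent$cfg$alpha0 * agent$cfg$alpha_c /
    (agent$cfg$alpha_c + agent$q_mf$visits[s, a])
  agent$q_mf <- mf_update(agent$q_mf, s, a, r, s_next, alpha,
                          agent$cfg$gamma)
  agent$model <- model_update(agent$model, s, a, r, s_next)
  agent$prev_action <- a
  agent$steps <- agent$steps + 1L
  if (agent$steps %% agent$cfg$plan_every == 0L) {
    agent$q_mb$values <- qmb_refresh(
      agent$q_mb$values, agent$model$counts, agent$model$pair_n,
      agent$model$r_sum, which(agent$model$pair_n > 0), agent$cfg$gamma,
      agent$cfg$plan_sweeps,
      kappa = if (agent$cfg$ablate_counterfactual) 0 else
        agent$cfg$plan_optimism)
  }
  agent
}
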