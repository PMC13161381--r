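# Meta-controller arbitration between the model-based and model-free
# pathways, the hybrid mixture identity, and the safety reflex.

#' Meta-controller state
#'
#' Holds the temperature of the sigmoid arbitration signal and the trigger
#' above which a counterfactual scan is forced before model-based selection.
#'
#' @param tau Temperature (> 0) scaling the disagreement variance.
#' @param lambda_trigger Threshold above which model-based selection is
#'   preceded by a counterfactual scan (default 0.7).
#' @param window Retained for an optional temporal variance variant
#'   (unused by the default per-state variance).
#' @return A `meta_controller`.
#' @export
meta_controller <- function(tau = 1.0, lambda_trigger = 0.7, window = 0L) {
  if (tau <= 0) stop("meta_controller: tau must be > 0", call. = FALSE)
  structure(list(tau = tau, lambda_trigger = lambda_trigger,
                 window = as.integer(window), lambda_history = numeric()),
            class = "meta_controller")
}

#' Arbitration signal lambda from pathway disagreement
#'
#' Computes `lambda = sigmoid(Var(Q_MB - Q_MF) / tau)` where the variance is
#' the population variance of the pathway disagreement over the action set
#' at the current state. Identical value rows give `lambda = 0.5`; growing
#' disagreement pushes `lambda` toward 1 (trust the planner), so the signal
#' always lies in `(0, 1)`.
#'
#' @param q_mb,q_mf Equal-length value vectors over the action set.
#' @param tau Temperature (> 0).
#' @return `lambda` in `(0, 1)`.
#' @export
meta_lambda <- function(q_mb, q_mf, tau = 1.0) {
  if (tau <= 0) stop("meta_lambda: tau must be > 0", call. = FALSE)
  if (length(q_mb) != length(q_mf) || length(q_mb) < 1L) {
    stop("meta_lambda: value vectors must have equal length >= 1",
         call. = FALSE)
  }
  d <- q_mb - q_mf
  v <- mean((d - mean(d))^2)   # population variance
  stats::plogis(v / tau)
}

#' Arbitrate between the model-based and model-free branch
#'
#' Draws a uniform number and routes to the model-based branch iff it is
#' `<= lambda`; the long-run model-based fraction therefore equals `lambda`.
#'
#' @param lambda Mixing weight in `[0, 1]`.
#' @return `"MB"` or `"MF"`.
#' @export
arbitrate <- function(lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("arbitrate: lambda must lie in [0, 1]", call. = FALSE)
  }
  if (stats::runif(1) <= lambda) "MB" else "MF"
}

#' Hybrid value mixture
#'
#' The exact mixture identity `lambda * q_mb + (1 - lambda) * q_mf`.
#'
#' @param lambda Mixing weight in `[0, 1]`.
#' @param q_mb,q_mf Component values (finite).
#' @return The mixed value.
#' @export
hybrid_q <- function(lambda, q_mb, q_mf) {
  if (any(!is.finite(c(lambda, q_mb, q_mf)))) {
    stop("hybrid_q: non-finite input", call. = FALSE)
  }
  if (lambda < 0 || lambda > 1) {
    stop("hybrid_q: lambda must lie in [0, 1]", call. = FALSE)
  }
  lambda * q_mb + (1 - lambda) * q_mf
}

#' Safety reflex override
#'
#' The hardware-level ("cerebellar") check that bypasses the learned policy:
#' a wheelchair tilt beyond the configured safe angle triggers an immediate
#' corrective tilt action; an active motor failure triggers the brake plus a
#' caregiver alert (the tilt actuator being down, correction is impossible).
#' Returns `NULL` when no override applies. Every override is logged by the
#' caller as a `reflex_override` event.
#'
#' @param tilt_unsafe Logical: tilt currently beyond the safe angle.
#' @param motor_failure Logical: tilt actuator currently failed.
#' @return An action name (`"adjust_tilt"` or `"raise_alert"`) or `NULL`.
#' @export
safety_reflex <- function(tilt_unsafe, motor_failure) {
  if (isTRUE(motor_failure)) return("raise_alert")  # brake + alert
  if (isTRUE(tilt_unsafe)) return("adjust_tilt")
  NULL
}

#' Hybrid agent hyperparameters
#'
#' @param alpha0,alpha_c Learning-rate schedule
#'   `alpha(s,a) = alpha0 * alpha_c / (alpha_c + visits(s,a))`, which
#'   satisfies the Robbins-Monro conditions per pair.
#' @param gamma Discount factor.
#' @param epsilon_start,epsilon_floor,epsilon_decay_frac,epsilon_end,epsilon_end_frac
#'   Exploration schedule, front-loaded: exponential decay from
#'   `epsilon_start` to `epsilon_floor` over the first `epsilon_decay_frac`
#'   of episodes, a slower exponential decay to `epsilon_end` by
#'   `epsilon_end_frac` of episodes, then held (persistent exploration).
#'   Exploration applies to the whole selection stage, not just the
#'   model-free branch, so small-sample value flukes are always eventually
#'   resampled regardless of the arbitration state.
#' @param planning_depth Horizon of [mb_plan()] when called as a pure op.
#' @param plan_every,plan_sweeps Planner refresh cadence inside training:
#'   every `plan_every` environment steps the cached model-based table is
#'   re-swept `plan_sweeps` times (warm-started value iteration on the
#'   learned model).
#' @param plan_optimism Count-based optimism `kappa / sqrt(N(s,a))` added to
#'   planned rewards (reward units; the discomfort magnitude by default),
#'   keeping under-simulated interventions competitive until tried.
#' @param tau Meta-controller temperature.
#' @param lambda_trigger Counterfactual-scan trigger on lambda.
#' @param cf_threshold Counterfactual advantage threshold (reward units).
#' @param cf_bonus Optional retry optimism `cf_bonus / sqrt(1 + visits)`
#'   applied to candidate values inside the lambda-triggered scan (0 by
#'   default: whole-pipeline epsilon exploration already resamples thin
#'   estimates, and a persistent scan bonus was found to churn mid-visit
#'   actions in states where the pathways disagree on scale).
#' @param fixed_lambda Fixed mixing weight used when the meta-controller is
#'   ablated (0.7 model-based / 0.3 model-free).
#' @param q_init Initial Q value (0; set > 0 for optimistic initialisation).
#' @param ablate_meta,ablate_counterfactual,ablate_rules Component switches.
#' @param reflex Enable the safety reflex.
#' @return A `hybrid_config` list.
#' @export
hybrid_config <- function(alpha0 = 0.1, alpha_c = 100, gamma = 0.95,
                          epsilon_start = 1.0, epsilon_floor = 0.05,
                          epsilon_decay_frac = 0.05, epsilon_end = 0.005,
                          epsilon_end_frac = 0.3,
                          planning_depth = 30L, plan_every = 25L,
                          plan_sweeps = 4L, plan_optimism = 1,
                          tau = 1.0, lambda_trigger = 0.7,
                          cf_threshold = 0.05, cf_bonus = 0,
                          fixed_lambda = 0.7, q_init = 0,
                          ablate_meta = FALSE, ablate_counterfactual = FALSE,
                          ablate_rules = FALSE, reflex = TRUE) {
  stopifnot(gamma > 0, gamma < 1, tau > 0, epsilon_floor >= 0,
            epsilon_start >= epsilon_floor, plan_every >= 1)
  structure(as.list(environment()), class = "hybrid_config")
}

epsilon_schedule <- function(agent, episode, episodes) {
  cut <- max(1, round(agent$epsilon_decay_frac * episodes))
  cut2 <- max(cut + 1, round(agent$epsilon_end_frac * episodes))
  if (episode < cut) {
    return(agent$epsilon_start *
             (agent$epsilon_floor / agent$epsilon_start)^((episode - 1) / cut))
  }
  if (episode >= cut2) return(agent$epsilon_end)
  agent$epsilon_floor *
    (agent$epsilon_end / agent$epsilon_floor)^((episode - cut) /
                                                 (cut2 - cut))
}
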