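# Tabular Q-learning and model-learning primitives.
#
# QTable and TransitionModel are plain S3 lists holding dense matrices keyed
# by discrete state index; absent pairs read as the initial value (QTable)
# or as flagged-uniform transitions (TransitionModel).

#' Create an empty Q table
#'
#' @param n_states,n_actions Table dimensions.
#' @param initial Initial value for every (state, action) pair; 0 by
#'   default, set positive for optimistic initialisation.
#' @return A `q_table` with `values` and `visits` matrices.
#' @export
q_table <- function(n_states, n_actions, initial = 0) {
  structure(list(values = matrix(initial, n_states, n_actions),
                 visits = matrix(0L, n_states, n_actions),
                 initial = initial),
            class = "q_table")
}

#' Model-free Q-update (temporal-difference backup)
#'
#' The classical tabular backup
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * max_a' Q(s',a') - Q(s,a))`.
#' Only the `(s, a)` entry changes; the visit count for the pair is
#' incremented.
#'
#' @param q A [q_table()].
#' @param s,a State and action indices.
#' @param r Observed reward (must be finite).
#' @param s_next Successor state index.
#' @param alpha Learning rate in `[0, 1]`.
#' @param gamma Discount factor in `(0, 1)`.
#' @return The updated `q_table`.
#' @export
mf_update <- function(q, s, a, r, s_next, alpha, gamma) {
  stopifnot(alpha >= 0, alpha <= 1, gamma > 0, gamma < 1)
  if (!is.finite(r)) stop("non-finite reward in mf_update", call. = FALSE)
  target <- r + gamma * max(q$values[s_next, ])
  q$values[s, a] <- q$values[s, a] + alpha * (target - q$values[s, a])
  q$visits[s, a] <- q$visits[s, a] + 1L
  q
}

#' Epsilon-greedy model-free action selection
#'
#' With probability `1 - epsilon` picks the argmax of the Q row over the
#' allowed actions (ties break to the lowest action id); otherwise picks
#' uniformly among the allowed actions.
#'
#' @param q A [q_table()].
#' @param s State index.
#' @param epsilon Exploration probability.
#' @param allowed Integer vector of permitted action ids (non-empty).
#' @return A single action id.
#' @export
mf_select <- function(q, s, epsilon, allowed = seq_len(ncol(q$values))) {
  if (length(allowed) == 0L) {
    stop("mf_select: empty allowed-action set", call. = FALSE)
  }
  if (stats::runif(1) < epsilon) {
    return(allowed[sample.int(length(allowed), 1L)])
  }
  vals <- q$values[s, allowed]
  allowed[which.max(vals)]
}

#' Create an empty learned transition/reward model
#'
#' Holds visit counts `N(s, a, s')`, pair counts `N(s, a)` and running
#' reward sums, from which empirical transition probabilities
#' `N(s,a,s')/N(s,a)` and mean rewards are derived.
#'
#' @param n_states,n_actions Model dimensions.
#' @return A `transition_model`.
#' @export
transition_model <- function(n_states, n_actions) {
  structure(list(
    counts = matrix(0, n_states * n_actions, n_states),
    pair_n = numeric(n_states * n_actions),
    r_sum = numeric(n_states * n_actions),
    n_states = as.integer(n_states), n_actions = as.integer(n_actions)
  ), class = "transition_model")
}

sa_row <- function(m, s, a) (a - 1L) * m$n_states + s

#' Record one observed transition in the learned model
#'
#' @param m A [transition_model()].
#' @param s,a,s_next Observed state, action, successor.
#' @param r Observed reward.
#' @return The updated model.
#' @export
model_update <- function(m, s, a, r, s_next) {
  i <- sa_row(m, s, a)
  m$counts[i, s_next] <- m$counts[i, s_next] + 1
  m$pair_n[i] <- m$pair_n[i] + 1
  m$r_sum[i] <- m$r_sum[i] + r
  m
}

#' Empirical transition probability
#'
#' Returns `N(s,a,s')/N(s,a)` when the pair has been observed. For an
#' unobserved pair the estimate falls back to a uniform distribution over
#' the action-reachable state set (states ever observed as successors of
#' `s`, or all states if none) and is flagged, not treated as an error.
#'
#' @param m A [transition_model()].
#' @param s,a,s_next Query triple.
#' @return List with `p` (probability) and `observed` (logical flag).
#' @export
transition_prob <- function(m, s, a, s_next) {
  i <- sa_row(m, s, a)
  if (m$pair_n[i] > 0) {
    return(list(p = m$counts[i, s_next] / m$pair_n[i], observed = TRUE))
  }
  rows <- sa_row(m, s, seq_len(m$n_actions))
  reach <- which(colSums(m$counts[rows, , drop = FALSE]) > 0)
  if (length(reach) == 0L) reach <- seq_len(m$n_states)
  list(p = as.numeric(s_next %in% reach) / length(reach), observed = FALSE)
}

# Normalised model views used by planning; unobserved pairs get NA rows.
model_probs <- function(m) {
  p <- m$counts / ifelse(m$pair_n > 0, m$pair_n, NA_real_)
  r <- m$r_sum / ifelse(m$pair_n > 0, m$pair_n, NA_real_)
  list(P = p, R = r)
}

#' Depth-limited planning on the learned model
#'
#' Finite-horizon value iteration on the empirical transition and reward
#' model, started from scratch (`V = 0`) and backed up `depth` times.
#' Unobserved (state, action) pairs contribute value 0 (the table initial
#' value) rather than a fabricated estimate. This is the model-based
#' ("prefrontal") pathway: the agent simulates consequences on its internal
#' model rather than reading cached values.
#'
#' @param m A [transition_model()].
#' @param s State to plan from.
#' @param depth Planning horizon (>= 1).
#' @param gamma Discount factor.
#' @return List with `q` (action values at `s`), `best` (argmax action,
#'   ties to lowest id), and `V` (state values at the planning root depth).
#' @export
mb_plan <- function(m, s, depth = 10L, gamma = 0.95) {
  stopifnot(depth >= 1)
  mp <- model_probs(m)
  P <- mp$P
  P[is.na(P)] <- 0           # unobserved pairs back up 0
  R <- ifelse(is.na(mp$R), 0, mp$R)
  nS <- m$n_states; nA <- m$n_actions
  V <- numeric(nS)
  Q <- matrix(0, nS, nA)
  for (d in seq_len(depth)) {
    ev <- as.numeric(P %*% V)
    Q <- matrix(R + gamma * ev, nS, nA)
    V <- do.call(pmax, lapply(seq_len(nA), function(a) Q[, a]))
  }
  list(q = Q[s, ], best = which.max(Q[s, ]), V = V)
}

#' Counterfactual action scan
#'
#' Evaluates the non-taken actions on the learned model and ranks them by
#' advantage over the currently-executing (incumbent) action:
#' `advantage(a) = Q_MB(s, a) - Q_MB(s, incumbent)`. Actions whose advantage
#' exceeds `threshold` are returned in descending order; when none do, the
#' full set is returned unranked with `prioritized = FALSE`. An optional
#' optimism bonus `bonus / sqrt(1 + visits)` widens the scan toward
#' insufficiently simulated actions (directed exploration); the default
#' `bonus = 0` gives the pure model advantage.
#'
#' @param m A [transition_model()].
#' @param s State index.
#' @param incumbent Currently-executing action id.
#' @param actions Candidate action ids (non-empty).
#' @param gamma Discount factor for the underlying plan.
#' @param threshold Advantage threshold (reward units).
#' @param depth Planning depth passed to [mb_plan()].
#' @param visits Optional visit-count vector (one per candidate action).
#' @param bonus Optimism scale; 0 disables.
#' @param q_mb Optional precomputed model value row (skips [mb_plan()]).
#' @return Tibble with columns `action`, `advantage`, ordered as described,
#'   plus attribute `prioritized`.
#' @export
counterfactual_scan <- function(m, s, incumbent, actions = seq_len(m$n_actions),
                                gamma = 0.95, threshold = 0.05, depth = 10L,
                                visits = NULL, bonus = 0, q_mb = NULL) {
  if (length(actions) == 0L) {
    stop("counterfactual_scan: empty action set", call. = FALSE)
  }
  if (is.null(q_mb)) q_mb <- mb_plan(m, s, depth = depth, gamma = gamma)$q
  q_eff <- q_mb[actions]
  if (bonus > 0 && !is.null(visits)) {
    q_eff <- q_eff + bonus / sqrt(1 + visits)
  }
  inc_val <- q_eff[match(incumbent, actions)]
  if (is.na(inc_val)) inc_val <- q_mb[incumbent]
  adv <- q_eff - inc_val
  hit <- adv > threshold
  if (any(hit)) {
    ord <- order(adv[hit], decreasing = TRUE)
    out <- tibble::tibble(action = actions[hit][ord],
                          advantage = adv[hit][ord])
    attr(out, "prioritized") <- TRUE
  } else {
    out <- tibble::tibble(action = actions, advantage = adv)
    attr(out, "prioritized") <- FALSE
  }
  out
}
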