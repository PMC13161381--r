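#' Packaged toy MDP fixture
#'
#' A small deterministic four-state, two-action ring MDP with known optimal
#' values, used throughout the test suite as an oracle fixture: action 1
#' advances around the ring (reward +1 on completing the loop from state 4),
#' action 2 stays in place for a small reward. With `gamma = 0.95` the
#' optimal policy advances from every state.
#'
#' @param stay_reward Reward for the stay action (default 0.05).
#' @param loop_reward Reward for advancing from state 4 back to state 1.
#' @return A `tabular_mdp` (see [care_mdp()] for the structure).
#' @export
toy_mdp <- function(stay_reward = 0.05, loop_reward = 1) {
  n <- 4L
  adv <- matrix(0, n, n)
  for (s in seq_len(n)) adv[s, s %% n + 1L] <- 1
  stay <- diag(n)
  R <- cbind(c(0, 0, 0, loop_reward), rep(stay_reward, n))
  structure(list(P = list(adv, stay), R = R, start = 1L,
                 n_states = n, n_actions = 2L,
                 actions = c("advance", "stay"), obs_map = seq_len(n)),
            class = "tabular_mdp")
}

#' Value iteration on a tabular MDP
#'
#' Standard infinite-horizon discounted value iteration, run to a sup-norm
#' tolerance on the value function. Serves as the package's planning and
#' evaluation oracle on true dynamics.
#'
#' @param mdp A `tabular_mdp`.
#' @param gamma Discount factor in `(0, 1)`.
#' @param tol Sup-norm convergence tolerance (on successive V).
#' @param max_iter Iteration cap.
#' @return List with `Q` (`n_states x n_actions`), `V`, and greedy `policy`
#'   (ties to the lowest action id).
#' @export
value_iteration <- function(mdp, gamma = 0.95, tol = 1e-8, max_iter = 10000L) {
  stopifnot(gamma >= 0, gamma < 1)
  V <- numeric(mdp$n_states)
  for (it in seq_len(max_iter)) {
    Q <- mdp$R
    for (a in seq_len(mdp$n_actions)) {
      Q[, a] <- mdp$R[, a] + gamma * as.numeric(mdp$P[[a]] %*% V)
    }
    V_new <- do.call(pmax, lapply(seq_len(mdp$n_actions), function(a) Q[, a]))
    if (max(abs(V_new - V)) < tol) {
      V <- V_new
      break
    }
    V <- V_new
  }
  list(Q = Q, V = V, policy = max.col(Q, ties.method = "first"))
}

# Finite-horizon undiscounted (or discounted) backward DP; returns the
# expected optimal return per state over `horizon` steps.
finite_horizon_values <- function(mdp, horizon, gamma = 1) {
  V <- numeric(mdp$n_states)
  for (t in seq_len(horizon)) {
    Q <- mdp$R
    for (a in seq_len(mdp$n_actions)) {
      Q[, a] <- mdp$R[, a] + gamma * as.numeric(mdp$P[[a]] %*% V)
    }
    V <- do.call(pmax, lapply(seq_len(mdp$n_actions), function(a) Q[, a]))
  }
  V
}
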