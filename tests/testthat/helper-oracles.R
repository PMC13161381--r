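# Independent oracles used to check the package's planners and metrics.
# These deliberately avoid the package's own value_iteration() internals:
# brute-force recursive expectimax for small horizons, and a naive
# fixed-point sweep for discounted values.

# exhaustive finite-horizon optimal value by recursion (tiny MDPs only)
oracle_fh_value <- function(P, R, s, depth, gamma) {
  if (depth == 0L) return(0)
  best <- -Inf
  for (a in seq_along(P)) {
    nxt <- 0
    for (s2 in seq_len(ncol(P[[a]]))) {
      p <- P[[a]][s, s2]
      if (p > 0) nxt <- nxt + p * oracle_fh_value(P, R, s2, depth - 1L, gamma)
    }
    best <- max(best, R[s, a] + gamma * nxt)
  }
  best
}

# naive Jacobi sweeps to a fixed point (independent of the package's VI)
oracle_discounted_q <- function(P, R, gamma, sweeps = 5000L) {
  n <- nrow(R)
  V <- numeric(n)
  Q <- R
  for (k in seq_len(sweeps)) {
    for (a in seq_along(P)) Q[, a] <- R[, a] + gamma * as.numeric(P[[a]] %*% V)
    V <- apply(Q, 1L, max)
  }
  Q
}

# small test configuration: a ward that runs fast
tiny_config <- function(...) {
  ward_config(grid_width = 12, grid_height = 12, n_patients = 4,
              n_caregivers = 2, n_env_controllers = 2, episodes = 5,
              steps_per_episode = 20, ...)
}

# a chart built directly (bypassing the simulator) for rule/discretize tests
synthetic_chart <- function(heart_rate = 80, blood_pressure = 110,
                            oxygen = 97, sugar = 100, temperature = 36.6,
                            tilt_angle = 10, emotional_score = 5,
                            expression = "Neutral",
                            intention = "routine_care") {
  structure(list(
    patient_id = 1L, step = 0L,
    X_tm = c("S1=G80.1 spastic quadriplegia", "Spasticity"),
    X_ti = intention,
    X_tr = list(prescriptions = "P1=Physical therapy",
                recent_actions = character()),
    P_ct = list(env_sensors = list(light = 300, fire = FALSE,
                                   temperature = temperature, smoke = FALSE),
                posture = list(DP_Wa = FALSE, EP_Wa = FALSE,
                               UP_Wa = tilt_angle > 25),
                facial_expression = expression),
    P_states = list(body_sensors = list(heart_rate = heart_rate,
                                        oxygen = oxygen,
                                        blood_pressure = blood_pressure,
                                        sugar = sugar),
                    tilt_angle = tilt_angle,
                    emotional_score = emotional_score)
  ), class = "cognitive_chart")
}
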