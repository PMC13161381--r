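# Baseline agents: pure model-free, pure model-based, and a small neural
# Q-learner ("DQN-lite": two 32-unit hidden layers, replay buffer, periodic
# target copy) trained on the identical care loop and event streams.

obs_unpack_features <- function() {
  # one-hot features of the 288 observed regimes: 3+3+2+2+2+2+2 = 16 dims
  F <- matrix(0, N_OBS, 16L)
  idx <- seq_len(N_OBS) - 1L
  lv <- c(3L, 3L, 2L, 2L, 2L, 2L, 2L)
  off <- 0L
  for (f in seq_along(lv)) {
    val <- idx %% lv[f]
    F[cbind(seq_len(N_OBS), off + val + 1L)] <- 1
    idx <- idx %/% lv[f]
    off <- off + lv[f]
  }
  F
}

#' Train the DQN-lite baseline on the care loop
#'
#' A desk-scale neural Q-learner: 16-dim one-hot regime features, two
#' 32-unit ReLU layers, experience replay (capacity 10^4, minibatch 32),
#' a target network copied every 500 steps, plain SGD, and the same epsilon
#' schedule and event streams as the tabular agents. Deterministic given
#' the seed.
#'
#' @param config A [ward_config()].
#' @param seed Run seed.
#' @param episodes Override the configured episode count.
#' @param lr SGD learning rate.
#' @param gamma Discount factor.
#' @param buffer_size,batch_size,target_sync Replay and target-copy knobs.
#' @param agent A [hybrid_config()] supplying the epsilon schedule.
#' @return A `ward_fit` (mode `"dqn_lite"`) with the per-episode log.
#' @export
train_dqn_lite <- function(config, seed = config$seed,
                           episodes = config$episodes, lr = 0.01,
                           gamma = 0.95, buffer_size = 10000L,
                           batch_size = 32L, target_sync = 500L,
                           agent = hybrid_config()) {
  Tn <- config$steps_per_episode
  nA <- N_ACT
  F <- obs_unpack_features()
  nf <- ncol(F)
  set.seed(sub_seed(seed, 30L))
  W1 <- matrix(stats::rnorm(nf * 32, 0, sqrt(2 / nf)), nf, 32)
  b1 <- numeric(32)
  W2 <- matrix(stats::rnorm(32 * 32, 0, sqrt(2 / 32)), 32, 32)
  b2 <- numeric(32)
  W3 <- matrix(stats::rnorm(32 * nA, 0, sqrt(2 / 32)), 32, nA)
  b3 <- numeric(nA)
  tg <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)

  fwd <- function(X, p) {
    H1 <- pmax(sweep(X %*% p$W1, 2, p$b1, "+"), 0)
    H2 <- pmax(sweep(H1 %*% p$W2, 2, p$b2, "+"), 0)
    list(H1 = H1, H2 = H2, Q = sweep(H2 %*% p$W3, 2, p$b3, "+"))
  }

  buf <- matrix(0L, buffer_size, 3L)   # s, a, s2
  buf_r <- numeric(buffer_size)
  bn <- 0L; bpos <- 0L
  gstep <- 0L
  start_lat <- c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)
  ep_log <- vector("list", episodes)

  for (ep in seq_len(episodes)) {
    set.seed(sub_seed(seed, 10L, ep))
    U <- matrix(stats::runif(Tn * 8L), Tn, 8L)
    set.seed(sub_seed(seed, 50L, ep))
    A <- matrix(stats::runif(Tn * 2L), Tn, 2L)
    eps <- epsilon_schedule(agent, ep, episodes)
    lat <- start_lat
    ret <- 0; falls <- 0L

    for (t in seq_len(Tn)) {
      s <- obs_pack(lat[1L], lat[2L], lat[3L], lat[4L],
                    1L + (lat[5L] > 1L), lat[6L], lat[7L])
      if (A[t, 1L] < eps) {
        a <- 1L + (ceiling(A[t, 2L] * nA) - 1L) %% nA
      } else {
        q1 <- fwd(F[s, , drop = FALSE],
                  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                       W3 = W3, b3 = b3))$Q
        a <- which.max(q1[1L, ])
      }
      res <- clin_step1(lat, a, U[t, ], config)
      lat <- res$lat
      s2 <- obs_pack(lat[1L], lat[2L], lat[3L], lat[4L],
                     1L + (lat[5L] > 1L), lat[6L], lat[7L])
      ret <- ret + res$reward
      if (res$fall) falls <- falls + 1L

      bpos <- bpos %% buffer_size + 1L
      buf[bpos, ] <- c(s, a, s2)
      buf_r[bpos] <- res$reward
      bn <- min(bn + 1L, buffer_size)
      gstep <- gstep + 1L

      if (bn >= 10L * batch_size) {
        idx <- sample.int(bn, batch_size)
        sb <- buf[idx, 1L]; ab <- buf[idx, 2L]; s2b <- buf[idx, 3L]
        X <- F[sb, , drop = FALSE]
        f1 <- fwd(X, list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                          W3 = W3, b3 = b3))
        q2 <- fwd(F[s2b, , drop = FALSE], tg)$Q
        y <- buf_r[idx] + gamma * apply(q2, 1L, max)
        dQ <- matrix(0, batch_size, nA)
        sel <- cbind(seq_len(batch_size), ab)
        dQ[sel] <- (f1$Q[sel] - y) / batch_size
        dW3 <- crossprod(f1$H2, dQ); db3 <- colSums(dQ)
        dH2 <- (dQ %*% t(W3)) * (f1$H2 > 0)
        dW2 <- crossprod(f1$H1, dH2); db2 <- colSums(dH2)
        dH1 <- (dH2 %*% t(W2)) * (f1$H1 > 0)
        dW1 <- crossprod(X, dH1); db1 <- colSums(dH1)
        W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
        W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
        W3 <- W3 - lr * dW3; b3 <- b3 - lr * db3
      }
      if (gstep %% target_sync == 0L) {
        tg <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
      }
    }
    ep_log[[ep]] <- c(episode = ep, return_ = ret, falls = falls,
                      lambda_mean = NA, mb_frac = NA, mf_frac = NA,
                      reflex_frac = 0, scans = 0, rules_forced = 0,
                      epsilon = eps)
  }
  log <- tibble::as_tibble(do.call(rbind, ep_log))
  names(log)[names(log) == "return_"] <- "return"
  structure(list(log = log, step_log = NULL, q_mf = NULL, q_mb = NULL,
                 visits = NULL, model = NULL, config = config,
                 agent = agent, seed = seed, mode = "dqn_lite",
                 episodes = episodes),
            class = "ward_fit")
}

#' Run a baseline agent
#'
#' Trains one of the packaged baselines on the care loop under one or more
#' seeds: `"mf_only"` (pure epsilon-greedy tabular Q-learning, no model, no
#' reflex, no rules), `"mb_only"` (pure planner on the learned model with
#' epsilon exploration), or `"dqn_lite"` (see [train_dqn_lite()]).
#'
#' @param kind Baseline name.
#' @param config A [ward_config()].
#' @param seeds Integer vector of run seeds.
#' @param agent A [hybrid_config()] (epsilon schedule and, for `mb_only`,
#'   planning knobs).
#' @param episodes Override the configured episode count.
#' @return A tibble with one [glance()] row per seed; the fitted objects
#'   are attached as attribute `"fits"`.
#' @export
run_baseline <- function(kind, config, seeds = config$seed,
                         agent = hybrid_config(),
                         episodes = config$episodes) {
  if (!kind %in% c("mf_only", "mb_only", "dqn_lite")) {
    stop("run_baseline: unknown baseline kind '", kind, "'", call. = FALSE)
  }
  fits <- lapply(seeds, function(sd) {
    if (kind == "dqn_lite") {
      train_dqn_lite(config, seed = sd, episodes = episodes, agent = agent)
    } else {
      run_care_loop(config, agent, sd, kind, episodes)
    }
  })
  out <- dplyr::bind_rows(lapply(fits, glance))
  attr(out, "fits") <- fits
  out
}
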