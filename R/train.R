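# Training loops. run_care_loop() is the workhorse: one patient's care loop
# simulated at the clinical-regime level, with the hybrid agent (or a
# baseline) acting each step. Exogenous clinical draws come from an
# event-stream substream derived only from (seed, episode), so paired runs
# of different agents face identical event streams (common random numbers).

# Scalar twin of clin_step() for the hot loop; equivalence is unit-tested.
clin_step1 <- function(lat, a, u, cfg) {
  r <- cfg$vitals_rates
  rw <- cfg$rewards
  hr <- lat[1L]; bp <- lat[2L]; spo2 <- lat[3L]; temp <- lat[4L]
  tilt <- lat[5L]; dis <- lat[6L]; due <- lat[7L]; mf <- lat[8L]

  if (hr == 3L) {
    dp <- if (a == 6L) r$hr_down_p2 else r$hr_down_spont
    hr2 <- if (u[1L] < dp) 2L else 3L
  } else if (hr == 1L) {
    hr2 <- if (u[1L] < r$hr_low_rec) 2L else 1L
  } else {
    up <- r$hr_up + if (temp == 2L) r$hr_up_fever else 0
    hr2 <- if (u[1L] < up) 3L else if (u[1L] > 1 - r$hr_low) 1L else 2L
  }

  if (bp == 3L) {
    dp <- if (a == 6L) r$bp_down_p2 else r$bp_down_spont
    bp2 <- if (u[2L] < dp) 2L else 3L
  } else if (bp == 1L) {
    bp2 <- if (u[2L] < r$bp_low_rec) 2L else 1L
  } else {
    bp2 <- if (u[2L] < r$bp_up) 3L else if (u[2L] > 1 - r$bp_low) 1L else 2L
  }

  if (spo2 == 1L) {
    rec <- if (a == 7L) r$spo2_rec_alert else r$spo2_rec_spont
    spo22 <- if (u[3L] < rec) 2L else 1L
  } else {
    spo22 <- if (u[3L] < r$spo2_drop) 1L else 2L
  }

  if (temp == 2L) {
    cool <- if (a == 4L) r$fever_cool else r$fever_spont
    temp2 <- if (u[4L] < cool) 1L else 2L
  } else {
    temp2 <- if (u[4L] < cfg$rate_fever) 2L else 1L
  }

  mf_on <- mf == 2L
  corrected <- a == 2L && !mf_on
  braked <- a == 7L && mf_on
  fall <- tilt == 3L && !corrected && !braked
  tilt2 <- if (corrected) 1L else if (braked) tilt else
    if (tilt == 1L) (if (u[5L] < r$tilt_drift) 2L else 1L) else
    if (tilt == 2L) 3L else 1L

  if (dis == 2L) {
    rec <- if (a == 3L) r$dis_rec_repo else r$dis_rec_spont
    dis2 <- if (u[6L] < rec) 1L else 2L
  } else {
    dis2 <- if (u[6L] < cfg$rate_distress) 2L else 1L
  }

  due2 <- if (due == 2L) (if (a == 5L) 1L else 2L) else
    (if (u[7L] < r$due_arrive) 2L else 1L)

  if (mf == 2L) {
    clr <- if (a == 7L) r$mf_clear_alert else r$mf_clear_spont
    mf2 <- if (u[8L] < clr) 1L else 2L
  } else {
    mf2 <- if (u[8L] < cfg$rate_motor_failure) 2L else 1L
  }

  nominal <- hr2 == 2L && bp2 == 2L && spo22 == 2L && temp2 == 1L &&
    tilt2 == 1L && dis2 == 1L
  reward <- rw$cost[[a]] +
    (if (a == 5L && due == 2L) rw$adherence else 0) +
    (if (fall) rw$fall else 0) +
    (if (temp2 == 2L) rw$hazard else 0) +
    rw$discomfort * ((dis2 == 2L) + (tilt2 > 1L) + (spo22 == 1L)) +
    (if (nominal) rw$comfort else 0)

  list(lat = unname(c(hr2, bp2, spo22, temp2, tilt2, dis2, due2, mf2)),
       reward = as.numeric(reward), fall = unname(fall),
       braked = unname(braked))
}

# Warm-started value-iteration sweeps on the learned model. Exploration is
# handled by count-based optimism (MBIE-EB style): planned rewards carry a
# kappa / sqrt(N(s,a)) bonus that decays as a pair is visited, and pairs
# never visited in a visited state back up a neutral self-loop value plus
# the full bonus, so untried interventions stay competitive until the model
# has actually simulated them.
qmb_refresh <- function(Qmb, counts, pair_n, r_sum, vis, gamma, sweeps,
                        kappa = 0) {
  if (length(vis) == 0L) return(Qmb)
  nS <- nrow(Qmb); nA <- ncol(Qmb)
  Cv <- counts[vis, , drop = FALSE]
  nv <- pair_n[vis]
  rhat <- r_sum[vis] / nv + kappa / sqrt(nv)
  seen <- which(rowSums(matrix(pair_n, nS, nA)) > 0)
  unvis <- setdiff(as.vector(outer(seen, (seq_len(nA) - 1L) * nS, "+")), vis)
  for (k in seq_len(sweeps)) {
    V <- Qmb[, 1L]
    for (j in 2:ncol(Qmb)) V <- pmax(V, Qmb[, j])
    Qmb[vis] <- rhat + gamma * as.numeric(Cv %*% V) / nv
    if (length(unvis)) {
      Qmb[unvis] <- kappa + gamma * V[(unvis - 1L) %% nS + 1L]
    }
  }
  Qmb
}

# mode: "hybrid", "mf_only", "mb_only"
run_care_loop <- function(config, agent = hybrid_config(), seed = config$seed,
                          mode = "hybrid", episodes = config$episodes,
                          log_steps = FALSE) {
  stopifnot(mode %in% c("hybrid", "mf_only", "mb_only"))
  Tn <- config$steps_per_episode
  nS <- N_OBS; nA <- N_ACT
  gamma <- agent$gamma
  Qmf <- matrix(agent$q_init, nS, nA)
  Qmb <- matrix(agent$q_init, nS, nA)
  visits <- matrix(0, nS, nA)
  counts <- matrix(0, nS * nA, nS)
  pair_n <- numeric(nS * nA)
  r_sum <- numeric(nS * nA)
  use_model <- mode != "mf_only"
  use_reflex <- mode == "hybrid" && isTRUE(agent$reflex)
  use_rules <- mode == "hybrid" && !agent$ablate_rules
  use_meta <- mode == "hybrid"
  use_cf <- mode == "hybrid" && !agent$ablate_counterfactual
  # counterfactual module = optimistic evaluation of under-simulated actions
  # on the learned model; ablating it leaves a plain greedy planner
  kappa <- if (use_cf) agent$plan_optimism else 0
  lam_fixed <- agent$ablate_meta

  ep_log <- vector("list", episodes)
  step_log <- if (log_steps) vector("list", episodes) else NULL
  start_lat <- c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)
  gstep <- 0L

  for (ep in seq_len(episodes)) {
    set.seed(sub_seed(seed, 10L, ep))
    U <- matrix(stats::runif(Tn * 8L), Tn, 8L)
    set.seed(sub_seed(seed, 20L, ep))
    A <- matrix(stats::runif(Tn * 3L), Tn, 3L)
    eps <- epsilon_schedule(agent, ep, episodes)
    lat <- start_lat
    prev_a <- 1L
    ret <- 0; falls <- 0L; lam_sum <- 0; n_mb <- 0L; n_mf <- 0L
    n_reflex <- 0L; n_scan <- 0L; n_forced <- 0L
    if (log_steps) {
      sl <- matrix(NA_real_, Tn, 12L)
      colnames(sl) <- c("step", "state", "action", "reward", "lambda",
                        "branch", "q_mb", "q_mf", "hybrid", "tilt_unsafe",
                        "motor_failure", "fall")
    }

    for (t in seq_len(Tn)) {
      s <- obs_pack(lat[1L], lat[2L], lat[3L], lat[4L],
                    1L + (lat[5L] > 1L), lat[6L], lat[7L])
      tilt_unsafe <- lat[5L] > 1L
      mf_on <- lat[8L] == 2L
      distress <- lat[6L] == 2L
      anomaly <- lat[1L] != 2L || lat[2L] != 2L || lat[3L] == 1L ||
        lat[4L] == 2L
      qmb_row <- Qmb[s, ]
      qmf_row <- Qmf[s, ]
      d <- qmb_row - qmf_row
      v <- mean((d - mean(d))^2)
      lambda <- if (lam_fixed) agent$fixed_lambda else
        stats::plogis(v / agent$tau)

      branch <- 0L  # 1 MB, 2 MF, 3 reflex
      a <- NA_integer_
      if (use_reflex && mf_on) {
        a <- 7L; branch <- 3L; n_reflex <- n_reflex + 1L
      } else if (use_reflex && tilt_unsafe) {
        a <- 2L; branch <- 3L; n_reflex <- n_reflex + 1L
      } else {
        mb_branch <- switch(mode,
          hybrid = distress || anomaly || A[t, 1L] <= lambda,
          mf_only = FALSE, mb_only = TRUE)
        if (use_rules && lat[4L] == 2L) {
          # fever: the symbolic layer forces the cooling protocol
          a <- 4L
          n_forced <- n_forced + 1L
          branch <- if (mb_branch) 1L else 2L
        } else if (A[t, 2L] < eps) {
          # the decision mechanism combines epsilon-greedy exploration with
          # the confidence arbitration: exploratory draws bypass both
          # branches. Gating exploration behind the model-free branch would
          # be self-defeating - a poisoned model value inflates the pathway
          # disagreement, saturates lambda, and would lock out the only
          # branch able to resample the poisoned pair.
          a <- 1L + (ceiling(A[t, 3L] * nA) - 1L) %% nA
          branch <- if (mb_branch) 1L else 2L
        } else if (mb_branch) {
          branch <- 1L
          if (use_cf && lambda > agent$lambda_trigger) {
            ucb <- qmb_row + agent$cf_bonus / sqrt(1 + visits[s, ])
            adv <- ucb - ucb[prev_a]
            n_scan <- n_scan + 1L
            a <- if (max(adv) > agent$cf_threshold) which.max(adv)
                 else which.max(qmb_row)
          } else {
            a <- which.max(qmb_row)
          }
        } else {
          branch <- 2L
          a <- which.max(qmf_row)
        }
      }
      if (branch == 1L) n_mb <- n_mb + 1L
      if (branch == 2L) n_mf <- n_mf + 1L

      res <- clin_step1(lat, a, U[t, ], config)
      r <- res$reward
      lat <- res$lat
      s2 <- obs_pack(lat[1L], lat[2L], lat[3L], lat[4L],
                     1L + (lat[5L] > 1L), lat[6L], lat[7L])
      ret <- ret + r
      if (res$fall) falls <- falls + 1L
      lam_sum <- lam_sum + lambda

      if (mode != "mb_only") {
        alpha <- agent$alpha0 * agent$alpha_c /
          (agent$alpha_c + visits[s, a])
        Qmf[s, a] <- Qmf[s, a] +
          alpha * (r + gamma * max(Qmf[s2, ]) - Qmf[s, a])
      }
      visits[s, a] <- visits[s, a] + 1
      if (use_model) {
        row <- (a - 1L) * nS + s
        counts[row, s2] <- counts[row, s2] + 1
        pair_n[row] <- pair_n[row] + 1
        r_sum[row] <- r_sum[row] + r
        gstep <- gstep + 1L
        if (gstep %% agent$plan_every == 0L) {
          Qmb <- qmb_refresh(Qmb, counts, pair_n, r_sum,
                             which(pair_n > 0), gamma, agent$plan_sweeps,
                             kappa = kappa)
        }
      }
      if (log_steps) {
        sl[t, ] <- c(t, s, a, r, lambda, branch, qmb_row[a], qmf_row[a],
                     hybrid_q(lambda, qmb_row[a], qmf_row[a]),
                     as.numeric(tilt_unsafe), as.numeric(mf_on),
                     as.numeric(res$fall))
      }
      prev_a <- a
    }
    ep_log[[ep]] <- c(episode = ep, return_ = ret, falls = falls,
                      lambda_mean = lam_sum / Tn, mb_frac = n_mb / Tn,
                      mf_frac = n_mf / Tn, reflex_frac = n_reflex / Tn,
                      scans = n_scan, rules_forced = n_forced, epsilon = eps)
    if (log_steps) {
      step_log[[ep]] <- tibble::as_tibble(sl) |>
        dplyr::mutate(episode = ep, .before = 1L)
    }
  }

  logm <- do.call(rbind, ep_log)
  log <- tibble::as_tibble(logm)
  names(log)[names(log) == "return_"] <- "return"
  model <- transition_model(nS, nA)
  model$counts <- counts; model$pair_n <- pair_n; model$r_sum <- r_sum

  structure(list(
    log = log,
    step_log = if (log_steps) dplyr::bind_rows(step_log) else NULL,
    q_mf = Qmf, q_mb = Qmb, visits = visits, model = model,
    config = config, agent = agent, seed = seed, mode = mode,
    episodes = episodes
  ), class = "ward_fit")
}

#' Train the hybrid agent on the packaged care loop
#'
#' Runs the full brain-inspired pipeline for `episodes` episodes of the
#' per-patient care loop: safety reflex, symbolic rule layer, sigmoid
#' meta-controller arbitration between the model-based planner (periodic
#' value-iteration sweeps on the learned empirical model, with a
#' counterfactual advantage scan above the lambda trigger) and the
#' epsilon-greedy model-free Q-learner.
#'
#' @param config A [ward_config()].
#' @param agent A [hybrid_config()].
#' @param seed Run seed (defaults to the config seed). Exogenous clinical
#'   event draws depend only on (seed, episode), so runs of different
#'   agents under one seed face identical event streams.
#' @param episodes Override the configured episode count.
#' @param log_steps Keep a per-step diagnostics log (state, action, reward,
#'   lambda, branch, pathway values and their hybrid mixture).
#' @return A `ward_fit` with a per-episode `log` tibble, the learned Q
#'   tables, visit counts and transition model.
#' @examples
#' cfg <- ward_config(episodes = 3, steps_per_episode = 20)
#' fit <- train_hybrid(cfg, seed = 1)
#' fit$log
#' @export
train_hybrid <- function(config, agent = hybrid_config(),
                         seed = config$seed, episodes = config$episodes,
                         log_steps = FALSE) {
  run_care_loop(config, agent, seed, "hybrid", episodes, log_steps)
}

#' @export
print.ward_fit <- function(x, ...) {
  cat(sprintf("<ward_fit:%s> %d episodes x %d steps, seed %d\n", x$mode,
              x$episodes, x$config$steps_per_episode, x$seed))
  n <- nrow(x$log)
  tail_band <- x$log$return[max(1, floor(n * 0.6)):n]
  cat(sprintf("  mean return (last 40%%): %.2f | falls total: %d | mean lambda: %.3f\n",
              mean(tail_band), sum(x$log$falls), mean(x$log$lambda_mean)))
  invisible(x)
}

#' Train the hybrid agent on an explicit tabular MDP
#'
#' Continuing-task trainer used for convergence studies on small fixtures
#' such as [toy_mdp()]: persistent epsilon exploration, Robbins-Monro
#' learning-rate schedule, learned transition model with periodic planning
#' sweeps, and sigmoid meta-arbitration between the pathways.
#'
#' @param mdp A `tabular_mdp`.
#' @param agent A [hybrid_config()].
#' @param steps Total environment steps.
#' @param seed Seed.
#' @param epsilon Persistent exploration rate.
#' @return List with `q_mf`, `q_mb`, `visits`, and `lambda_trace` summary.
#' @export
train_mdp_hybrid <- function(mdp, agent = hybrid_config(), steps = 2e5,
                             seed = 1L, epsilon = 0.1) {
  nS <- mdp$n_states; nA <- mdp$n_actions
  gamma <- agent$gamma
  cum <- lapply(mdp$P, function(P) t(apply(P, 1L, cumsum)))
  Qmf <- matrix(agent$q_init, nS, nA)
  Qmb <- matrix(agent$q_init, nS, nA)
  visits <- matrix(0, nS, nA)
  counts <- matrix(0, nS * nA, nS)
  pair_n <- numeric(nS * nA)
  r_sum <- numeric(nS * nA)
  set.seed(sub_seed(seed, 40L))
  s <- mdp$start
  prev_a <- 1L
  lam_sum <- 0
  U <- matrix(stats::runif(3 * steps), steps, 3L)
  for (t in seq_len(steps)) {
    qmb_row <- Qmb[s, ]; qmf_row <- Qmf[s, ]
    d <- qmb_row - qmf_row
    lambda <- if (agent$ablate_meta) agent$fixed_lambda else
      stats::plogis(mean((d - mean(d))^2) / agent$tau)
    lam_sum <- lam_sum + lambda
    if (U[t, 2L] < epsilon) {
      a <- 1L + (ceiling(U[t, 3L] * nA) - 1L) %% nA
    } else if (U[t, 1L] <= lambda) {
      if (!agent$ablate_counterfactual && lambda > agent$lambda_trigger) {
        ucb <- qmb_row + agent$cf_bonus / sqrt(1 + visits[s, ])
        adv <- ucb - ucb[prev_a]
        a <- if (max(adv) > agent$cf_threshold) which.max(adv)
             else which.max(qmb_row)
      } else {
        a <- which.max(qmb_row)
      }
    } else {
      a <- which.max(qmf_row)
    }
    s2 <- findInterval(stats::runif(1), cum[[a]][s, ]) + 1L
    r <- mdp$R[s, a]
    alpha <- agent$alpha0 * agent$alpha_c / (agent$alpha_c + visits[s, a])
    Qmf[s, a] <- Qmf[s, a] + alpha * (r + gamma * max(Qmf[s2, ]) - Qmf[s, a])
    visits[s, a] <- visits[s, a] + 1
    row <- (a - 1L) * nS + s
    counts[row, s2] <- counts[row, s2] + 1
    pair_n[row] <- pair_n[row] + 1
    r_sum[row] <- r_sum[row] + r
    if (t %% agent$plan_every == 0L) {
      Qmb <- qmb_refresh(Qmb, counts, pair_n, r_sum, which(pair_n > 0),
                         gamma, agent$plan_sweeps,
                         kappa = if (agent$ablate_counterfactual) 0 else
                           agent$plan_optimism)
    }
    prev_a <- a
    s <- s2
  }
  list(q_mf = Qmf, q_mb = Qmb, visits = visits,
       lambda_mean = lam_sum / steps)
}
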