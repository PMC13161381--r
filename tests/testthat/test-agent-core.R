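test_that("the Q backup reproduces hand-computed values and edge cases", {
  q <- q_table(4, 2)
  q1 <- mf_update(q, 1, 1, r = 1, s_next = 2, alpha = 0.1, gamma = 0.95)
  expect_equal(q1$values[1, 1], 0.1)          # zero bootstrap
  expect_equal(sum(q1$values != 0), 1L)       # only (s,a) changed

  q$values[1, 1] <- 0.5
  q$values[2, ] <- c(1, 0.2)
  q2 <- mf_update(q, 1, 1, r = 0, s_next = 2, alpha = 0.5, gamma = 0.95)
  expect_equal(q2$values[1, 1], 0.5 + 0.5 * (0.95 - 0.5))   # = 0.725

  q3 <- mf_update(q, 1, 1, r = 5, s_next = 2, alpha = 0, gamma = 0.95)
  expect_equal(q3$values, q$values)
  expect_error(mf_update(q, 1, 1, r = NaN, s_next = 2, alpha = 0.1,
                         gamma = 0.95), "non-finite")
})

test_that("epsilon-greedy selection is greedy, tie-broken low, and uniform", {
  q <- q_table(2, 4)
  q$values[1, ] <- c(0, 3, 1, 2)
  set.seed(1)
  expect_true(all(replicate(25, mf_select(q, 1, epsilon = 0)) == 2L))

  q$values[1, ] <- c(1, 3, 3, 0)              # tie between 2 and 3
  expect_equal(mf_select(q, 1, epsilon = 0), 2L)

  set.seed(2)
  draws <- replicate(10000, mf_select(q, 1, epsilon = 1))
  freq <- table(factor(draws, levels = 1:4)) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
  expect_error(mf_select(q, 1, 0.1, allowed = integer()), "empty")
})

test_that("the transition model counts, normalises and flags as specified", {
  m <- transition_model(5, 2)
  m <- model_update(m, 1, 1, r = 0.5, s_next = 2)
  expect_equal(m$pair_n[wardrl:::sa_row(m, 1, 1)], 1)
  expect_equal(m$counts[wardrl:::sa_row(m, 1, 1), 2], 1)

  for (k in 1:3) m <- model_update(m, 2, 1, 0, 3)
  m <- model_update(m, 2, 1, 0, 4)
  expect_equal(transition_prob(m, 2, 1, 3)$p, 0.75)
  expect_true(transition_prob(m, 2, 1, 3)$observed)
  # rows over observed successors sum to exactly 1
  i <- wardrl:::sa_row(m, 2, 1)
  expect_identical(sum(m$counts[i, ]) / m$pair_n[i], 1)

  un <- transition_prob(m, 2, 2, 3)           # action 2 never tried in s=2
  expect_false(un$observed)
  expect_equal(un$p, 0.5)                     # uniform over reachable {3,4}
})

test_that("empirical transition probabilities concentrate on the truth", {
  m <- transition_model(3, 1)
  set.seed(5)
  n <- 10000
  succ <- sample(c(2L, 3L), n, replace = TRUE, prob = c(0.7, 0.3))
  for (s2 in succ) m <- model_update(m, 1, 1, 0, s2)
  p <- transition_prob(m, 1, 1, 2)$p
  expect_lt(abs(p - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("depth-limited planning matches the brute-force oracle", {
  mdp <- toy_mdp()
  m <- transition_model(4, 2)
  # feed the exact dynamics into the empirical model
  for (s in 1:4) for (a in 1:2) {
    for (s2 in 1:4) {
      cnt <- round(1000 * mdp$P[[a]][s, s2])
      if (cnt > 0) for (k in seq_len(cnt)) {
        m <- model_update(m, s, a, mdp$R[s, a], s2)
      }
    }
  }
  deep <- mb_plan(m, 1, depth = 400, gamma = 0.95)
  oracle <- oracle_discounted_q(mdp$P, mdp$R, 0.95)
  expect_equal(deep$q, oracle[1, ], tolerance = 1e-6)
  expect_equal(deep$best, which.max(oracle[1, ]))

  shallow <- mb_plan(m, 4, depth = 1, gamma = 0.95)
  expect_equal(shallow$best, which.max(mdp$R[4, ]))   # horizon-1 reduction
})

test_that("planning on a deterministic chain finds the shortest rewarding path", {
  # states 1-2-3; advance reaches the rewarding terminal 3, stay idles
  P <- list(advance = rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 1)),
            stay = diag(3))
  R <- cbind(c(0, 1, 0), c(0, 0, 0))
  m <- transition_model(3, 2)
  for (s in 1:3) for (a in 1:2) {
    s2 <- which(P[[a]][s, ] == 1)
    for (k in 1:50) m <- model_update(m, s, a, R[s, a], s2)
  }
  plan <- mb_plan(m, 1, depth = 10, gamma = 0.95)
  expect_equal(plan$best, 1L)                 # advance toward the reward
  expect_equal(oracle_fh_value(P, R, 1, 10, 0.95),
               max(plan$q), tolerance = 1e-9)
})

test_that("counterfactual advantages equal Q* - V* on a known MDP", {
  mdp <- toy_mdp()
  m <- transition_model(4, 2)
  for (s in 1:4) for (a in 1:2) for (s2 in which(mdp$P[[a]][s, ] > 0)) {
    for (k in 1:100) m <- model_update(m, s, a, mdp$R[s, a], s2)
  }
  oracle <- oracle_discounted_q(mdp$P, mdp$R, 0.95)
  vstar <- max(oracle[2, ])
  greedy <- which.max(oracle[2, ])
  scan <- counterfactual_scan(m, 2, incumbent = greedy, actions = 1:2,
                              gamma = 0.95, threshold = -Inf, depth = 400)
  got <- scan$advantage[order(scan$action)]
  expect_equal(got, oracle[2, ] - vstar, tolerance = 1e-6)
})

test_that("the scan prioritises above threshold and flags the fallback", {
  m <- transition_model(2, 3)
  for (a in 1:3) for (k in 1:10) {
    m <- model_update(m, 1, a, c(0.5, 0.05, 0)[a], 2)
  }
  for (k in 1:10) m <- model_update(m, 2, 1, 0, 2)
  out <- counterfactual_scan(m, 1, incumbent = 3, actions = 1:3,
                             gamma = 0.95, threshold = 0.1, depth = 5)
  expect_true(attr(out, "prioritized"))
  expect_equal(out$action[1], 1L)             # only clear advantages kept
  expect_true(all(out$advantage > 0.1))

  out2 <- counterfactual_scan(m, 1, incumbent = 1, actions = 1:3,
                              gamma = 0.95, threshold = 10, depth = 5)
  expect_false(attr(out2, "prioritized"))
  expect_equal(sort(out2$action), 1:3)        # full set returned unranked
})
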