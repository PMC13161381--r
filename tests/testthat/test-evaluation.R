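test_that("the optimal-return oracle matches brute force and scales linearly", {
  mdp <- toy_mdp()
  vi <- optimal_return(mdp, gamma = 0.95, tol = 1e-10)
  oracle <- oracle_discounted_q(mdp$P, mdp$R, 0.95)
  expect_equal(vi$V, apply(oracle, 1, max), tolerance = 1e-7)

  greedy0 <- optimal_return(mdp, gamma = 0)     # closed form: max immediate
  expect_equal(greedy0$V, apply(mdp$R, 1, max))

  mdp2 <- mdp
  mdp2$R <- 2 * mdp$R
  expect_equal(optimal_return(mdp2, gamma = 0.95)$V,
               2 * optimal_return(mdp, gamma = 0.95)$V, tolerance = 1e-6)
})

test_that("a degenerate reward-free MDP warns but still evaluates", {
  mdp <- toy_mdp(stay_reward = 0, loop_reward = 0)
  expect_warning(out <- optimal_return(mdp, gamma = 0.9), "degenerate")
  expect_equal(out$start_value, 0)
})

test_that("regret and convergence metrics reduce to their closed forms", {
  expect_equal(regret_rate(rep(10, 5), 10), 0)
  expect_equal(regret_rate(rep(9, 5), 10), 10)
  expect_equal(regret_rate(c(12, 12), 10), 0)        # clipped at zero
  expect_error(regret_rate(1:5, 0), "positive")
  expect_error(regret_rate(1:5, c(1, 2)), "lengths")

  expect_equal(convergence_pct(rep(10, 10), 10, 1:10), 100)
  expect_equal(convergence_pct(c(5, 8, 10), 10, 3), 100)   # singleton band
  expect_error(convergence_pct(1:10, 10, integer()), "empty")
  expect_error(convergence_pct(1:10, 10, 5:15), "band")
})

test_that("fall counting recounts logs and rejects malformed records", {
  ev <- tibble::tibble(step = 1:5,
                       kind = c("fall", "fire", "fall", "distress", "fall"),
                       patient_id = 1:5, payload = "")
  expect_equal(count_falls(ev), 3L)
  expect_equal(count_falls(ev[ev$kind != "fall", ]), 0L)

  dir <- withr::local_tempdir()
  p <- file.path(dir, "log.jsonl")
  writeLines(c('{"episode":1,"step":1,"events":["fall"]}',
               '{"episode":1,"step":2,"events":[]}',
               '{"episode":1,"step":3,"events":["fall","reflex_override"]}'),
             p)
  expect_equal(count_falls(p), 2L)
  writeLines(c('{"ok":1}', '{broken'), p)
  expect_error(count_falls(p), "line 2")
})

test_that("sample efficiency computes first-crossing reductions", {
  g <- 10
  flat <- rep(10, 100)
  out <- sample_efficiency(flat, flat, g, steps_per_episode = 50)
  expect_equal(out$percent, 0)

  a <- c(rep(0, 80), rep(10, 120))   # full 20-ep window of 10s at ep 100
  b <- c(rep(0, 180), rep(10, 120))  # at ep 200
  out2 <- sample_efficiency(a, b, g, threshold_fraction = 1,
                            steps_per_episode = 50)
  expect_equal(out2$samples_a, 100 * 50)
  expect_equal(out2$samples_b, 200 * 50)
  expect_equal(out2$percent, 50)

  never <- rep(0, 200)
  out3 <- sample_efficiency(a, never, g, steps_per_episode = 50)
  expect_false(out3$reached_b)
  expect_true(is.na(out3$percent))
})

test_that("scorecard reproduces the published weighting and exact sums", {
  w <- reward_weights()
  # the published weights total 95% even though their table claims 100%
  expect_equal(100 * sum(w), 95, tolerance = 1e-12)
  expect_equal(scorecard(rep(100, 7))$combined, 95, tolerance = 1e-12)
  # the published component table: its true weighted sum is 93.0
  comps <- c(transferability = 98, robustness = 99, generalization = 98,
             sample_efficiency = 97, exploration_exploitation = 96,
             sensitivity = 99, interpretability = 98)
  expect_equal(scorecard(comps)$combined, 93.0, tolerance = 1e-12)

  w2 <- c(transferability = 0.5, robustness = 0.5, generalization = 0,
          sample_efficiency = 0, exploration_exploitation = 0,
          sensitivity = 0, interpretability = 0)
  expect_equal(scorecard(c(80, 100, 0, 0, 0, 0, 0), w2)$combined, 90)
  expect_error(scorecard(rep(50, 7), w2 * 2), "sum to 1")
  expect_error(scorecard(rep(150, 7)), "0, 100")
  # scaling all components scales the combination
  expect_equal(scorecard(comps / 2)$combined, 93.0 / 2)
})

test_that("ablations flip exactly one component switch", {
  ag <- hybrid_config()
  expect_true(ablate(ag, "meta")$ablate_meta)
  expect_false(ablate(ag, "meta")$ablate_counterfactual)
  expect_true(ablate(ag, "counterfactual")$ablate_counterfactual)
  expect_true(ablate(ag, "rules")$ablate_rules)
  expect_error(ablate(ag, "gravity"), "unknown component")
})

test_that("meta ablation fixes lambda at the 0.7 weighting", {
  cfg <- ward_config(episodes = 4, steps_per_episode = 25)
  fit <- train_hybrid(cfg, ablate(hybrid_config(), "meta"), seed = 1,
                      log_steps = TRUE)
  expect_true(all(fit$step_log$lambda == 0.7))
})

test_that("counterfactual ablation leaves no advantage scans in diagnostics", {
  cfg <- ward_config(episodes = 6, steps_per_episode = 30)
  fit <- train_hybrid(cfg, ablate(hybrid_config(), "counterfactual"),
                      seed = 1)
  expect_equal(sum(fit$log$scans), 0)
})

test_that("sensitivity sweeps report deviations against the default", {
  cfg <- ward_config(episodes = 6, steps_per_episode = 20)
  out <- sensitivity_sweep(cfg, list(alpha0 = 0.1), episodes = 6, seeds = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$deviation_pct, 0)          # grid point == default

  out3 <- sensitivity_sweep(cfg, list(alpha0 = c(0.01, 0.05, 0.1)),
                            episodes = 6, seeds = 1)
  expect_equal(nrow(out3), 3L)
  expect_error(sensitivity_sweep(cfg, list(warp_drive = 1)), "unknown")
  expect_error(sensitivity_sweep(cfg, list()), "empty")
})

test_that("report numbers are recomputable from the written artifacts", {
  cfg <- ward_config(episodes = 12, steps_per_episode = 30)
  fit <- train_hybrid(cfg, seed = 8)
  g <- episode_gstar(cfg)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "summary.csv")
  write_run_summary(fit, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), 12L)
  expect_equal(back$return, fit$log$return)
  expect_equal(regret_rate(back$return, g),
               regret_rate(fit$log$return, g))
  expect_equal(back$regret_pct, pmax(0, 100 * (g - back$return) / g))
})
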