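test_that("lambda is the sigmoid of scaled pathway disagreement", {
  expect_equal(meta_lambda(c(3, -1, 7), c(3, -1, 7)), 0.5)   # sigma(0)
  # population Var of [1,1,3,3] is 1 -> logistic(1)
  expect_equal(meta_lambda(c(1, 1, 3, 3), c(0, 0, 0, 0), tau = 1),
               0.7310586, tolerance = 1e-7)
  expect_equal(meta_lambda(c(1e6, -1e6), c(0, 0)), 1)        # sigmoid limit
  expect_error(meta_lambda(1:3, 1:3, tau = 0), "tau")
  expect_error(meta_lambda(1:3, 1:2), "equal length")
})

test_that("lambda is monotone in disagreement and in temperature", {
  vars <- seq(0.1, 5, by = 0.1)
  lams <- vapply(vars, function(v) {
    meta_lambda(c(sqrt(v), -sqrt(v)), c(0, 0), tau = 1)
  }, numeric(1))
  expect_true(all(diff(lams) > 0))
  expect_true(all(lams > 0 & lams < 1))

  taus <- c(0.5, 1, 2, 5)
  lams_tau <- vapply(taus, function(tt) {
    meta_lambda(c(1, -1), c(0, 0), tau = tt)
  }, numeric(1))
  expect_true(all(diff(lams_tau) < 0))
})

test_that("arbitration follows the mixing weight in the long run", {
  expect_true(all(replicate(20, arbitrate(1)) == "MB"))
  expect_true(all(replicate(20, arbitrate(0)) == "MF"))
  set.seed(3)
  n <- 1e5
  frac <- mean(replicate(n, arbitrate(0.7)) == "MB")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  expect_error(arbitrate(1.2), "lambda")
})

test_that("the hybrid mixture is exact", {
  expect_identical(hybrid_q(0.7, 2, 1), 0.7 * 2 + 0.3 * 1)   # 1.7
  expect_identical(hybrid_q(0, 5, -3), -3)
  expect_identical(hybrid_q(1, 5, -3), 5)
  expect_error(hybrid_q(0.5, Inf, 1), "non-finite")
  expect_error(hybrid_q(1.5, 1, 1), "lambda")
})

test_that("the safety reflex overrides on unsafe tilt and motor failure", {
  expect_identical(safety_reflex(TRUE, FALSE), "adjust_tilt")
  expect_identical(safety_reflex(FALSE, TRUE), "raise_alert")
  expect_identical(safety_reflex(TRUE, TRUE), "raise_alert")  # brake first
  expect_null(safety_reflex(FALSE, FALSE))
})

test_that("the exploration schedule decays through floor to end rate", {
  ag <- hybrid_config()
  eps <- vapply(1:500, function(ep) {
    wardrl:::epsilon_schedule(ag, ep, 500)
  }, numeric(1))
  expect_equal(eps[1], 1)
  expect_true(all(diff(eps) <= 1e-12))
  cut <- round(ag$epsilon_decay_frac * 500)
  expect_equal(eps[cut], ag$epsilon_floor, tolerance = 0.01)
  expect_equal(eps[500], ag$epsilon_end, tolerance = 1e-6)
})

test_that("the learning-rate schedule satisfies the Robbins-Monro conditions", {
  ag <- hybrid_config()
  n <- 1:200000
  alphas <- ag$alpha0 * ag$alpha_c / (ag$alpha_c + n)
  # partial sums grow without bound (harmonic) while squares converge
  expect_gt(sum(alphas), 50)
  expect_lt(sum(alphas^2), ag$alpha0^2 * ag$alpha_c * 2)
  expect_true(all(alphas <= ag$alpha0 & alphas > 0))
})
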