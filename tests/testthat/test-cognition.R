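test_that("charts are pure functions of the ward state", {
  w <- init_ward(tiny_config(seed = 21))
  c1 <- build_chart(w, 1)
  c2 <- build_chart(w, 1)
  expect_identical(c1, c2)
  expect_error(build_chart(w, 999), "unknown patient")
  # all five chart compartments populated
  expect_named(c1[c("X_tm", "X_ti", "X_tr", "P_ct", "P_states")],
               c("X_tm", "X_ti", "X_tr", "P_ct", "P_states"))
  expect_identical(c1$X_tr$recent_actions, character())
})

test_that("fever shows up in the chart context temperature", {
  w <- inject_event(init_ward(tiny_config(seed = 4)), "fever_spike", 1)
  out <- ward_step(w)
  expect_gt(build_chart(out$ward, 1)$P_ct$env_sensors$temperature, 38)
})

test_that("discretisation bins continuous fields at clinical thresholds", {
  expect_equal(discretize(synthetic_chart(heart_rate = 125))$bin_vector[["hr"]], 3L)
  expect_equal(discretize(synthetic_chart(heart_rate = 55))$bin_vector[["hr"]], 1L)
  expect_equal(discretize(synthetic_chart(blood_pressure = 145))$bin_vector[["bp"]], 3L)
  expect_equal(discretize(synthetic_chart(oxygen = 90))$bin_vector[["spo2"]], 1L)
  expect_equal(discretize(synthetic_chart(temperature = 38.5))$bin_vector[["temp"]], 2L)
  expect_equal(discretize(synthetic_chart(tilt_angle = 30))$bin_vector[["tilt"]], 2L)
  expect_equal(discretize(synthetic_chart(emotional_score = 40))$bin_vector[["distress"]], 2L)
  expect_equal(discretize(synthetic_chart(expression = "Crying"))$bin_vector[["distress"]], 2L)
  expect_equal(discretize(synthetic_chart(intention = "deliver_therapy"))$bin_vector[["therapy_due"]], 2L)
})

test_that("the nominal chart maps to a canonical stable index", {
  i1 <- discretize(synthetic_chart())$index
  i2 <- discretize(synthetic_chart(heart_rate = 95, blood_pressure = 120))$index
  expect_identical(i1, i2)
  expect_gte(i1, 1L)
  expect_lte(i1, n_discrete_states())
  # bijective mixed-radix encoding: distinct bins -> distinct indices
  idxs <- c(i1,
            discretize(synthetic_chart(heart_rate = 125))$index,
            discretize(synthetic_chart(temperature = 39))$index,
            discretize(synthetic_chart(tilt_angle = 35))$index,
            discretize(synthetic_chart(intention = "deliver_therapy"))$index)
  expect_equal(anyDuplicated(idxs), 0L)
})

test_that("out-of-bounds readings clip to the edge bin with a warning", {
  expect_warning(ds <- discretize(synthetic_chart(heart_rate = 300)),
                 "outside simulation bounds")
  expect_equal(ds$bin_vector[["hr"]], 3L)
})

test_that("clinical rules tag, force and reward as specified", {
  rules <- clinical_rules()
  ra <- apply_rules(rules, synthetic_chart(heart_rate = 125))
  expect_true(any(grepl("R00.0", ra$tags)))
  expect_null(ra$forced_action)

  ra2 <- apply_rules(rules, synthetic_chart(temperature = 38.5))
  expect_identical(ra2$forced_action, "activate_cooling")

  # adherence shaping via an explicit bonus rule
  bonus_rule <- tibble::tibble(
    id = "r90", field = "intention", op = "==", value = NA,
    effect = "bonus", action = "give_p1", label = NA, amount = 10,
    provenance = "therapy adherence")
  bonus_rule$value <- "deliver_therapy"
  ra3 <- apply_rules(bonus_rule,
                     synthetic_chart(intention = "deliver_therapy"))
  expect_equal(unname(ra3$shaping_bonus["give_p1"]), 10)
  expect_equal(unname(ra3$shaping_bonus["no_op"]), 0)
})

test_that("rule conflicts error and masks never empty the action set", {
  ch <- synthetic_chart(temperature = 39, heart_rate = 130)
  conflicting <- clinical_rules()
  conflicting <- rbind(conflicting, tibble::tibble(
    id = "r99", field = "heart_rate", op = ">", value = 120,
    effect = "force_action", action = "give_p2", label = NA, amount = NA,
    provenance = "test"))
  expect_error(apply_rules(conflicting, ch), "r03.*r99|conflicting")

  mask_all <- tibble::tibble(
    id = sprintf("m%02d", seq_along(ward_actions())),
    field = "heart_rate", op = ">", value = 0,
    effect = "mask_action", action = ward_actions(), label = NA,
    amount = NA, provenance = "test")
  ra <- apply_rules(mask_all, synthetic_chart())
  expect_identical(ra$allowed_actions, "no_op")
})

test_that("adding a mask rule never enlarges the allowed set", {
  base <- clinical_rules()
  ch <- synthetic_chart(heart_rate = 130, tilt_angle = 30)
  set.seed(8)
  for (k in 1:20) {
    extra <- tibble::tibble(
      id = "zz1", field = sample(c("heart_rate", "tilt_angle"), 1),
      op = ">", value = runif(1, 0, 200), effect = "mask_action",
      action = sample(ward_actions()[-1], 1), label = NA, amount = NA,
      provenance = "prop")
    a0 <- apply_rules(base, ch)$allowed_actions
    a1 <- apply_rules(rbind(base, extra), ch)$allowed_actions
    expect_true(all(a1 %in% a0))
  }
})

test_that("chart-level discretisation agrees with the simulator's state index", {
  cfg <- tiny_config(seed = 31, rate_fever = 0.2, rate_distress = 0.3,
                     vitals_rates = list(tilt_drift = 0.3))
  w <- init_ward(cfg)
  for (k in 1:6) {
    out <- ward_step(w)
    w <- out$ward
    for (pid in c(1, 3)) {
      lat <- w$lat[pid, ]
      expected <- wardrl:::obs_pack(lat[["hr"]], lat[["bp"]], lat[["spo2"]],
                                    lat[["temp"]], 1L + (lat[["tilt"]] > 1L),
                                    lat[["dis"]], lat[["due"]])
      got <- discretize(build_chart(w, pid), cfg$max_safe_angle)$index
      expect_identical(got, expected)
    }
  }
})
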