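test_that("ward initialisation places the configured agents at distinct cells", {
  ward <- init_ward(ward_config())
  expect_equal(nrow(ward$patients), 40L)
  expect_equal(nrow(ward$caregivers), 10L)
  expect_equal(nrow(ward$env_controllers), 21L)
  cells <- c(paste(ward$patients$x, ward$patients$y),
             paste(ward$caregivers$x, ward$caregivers$y),
             paste(ward$env_controllers$x, ward$env_controllers$y))
  expect_equal(anyDuplicated(cells), 0L)
  # stratified subtype rounding for the 40/30/15/15 mix
  expect_equal(unname(table(ward$patients$subtype)[c("S1", "S2", "S3", "S4")]),
               c(16L, 12L, 6L, 6L), ignore_attr = TRUE)
})

test_that("identical seeds give byte-identical serialized ward states", {
  cfg <- tiny_config(seed = 7)
  w1 <- init_ward(cfg)
  w2 <- init_ward(cfg)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  # and stepping stays deterministic
  s1 <- ward_step(w1)
  s2 <- ward_step(w2)
  expect_identical(serialize(s1$ward, NULL), serialize(s2$ward, NULL))
  expect_identical(s1$rewards, s2$rewards)
})

test_that("agent counts are conserved across steps", {
  cfg <- tiny_config(seed = 2)
  w <- init_ward(cfg)
  for (k in 1:10) w <- ward_step(w)$ward
  expect_equal(nrow(w$patients), cfg$n_patients)
  expect_equal(nrow(w$caregivers), cfg$n_caregivers)
  expect_equal(anyDuplicated(paste(w$patients$x, w$patients$y)), 0L)
})

test_that("injected events propagate to the next observation", {
  cfg <- tiny_config(seed = 5)
  w <- init_ward(cfg)
  w <- inject_event(w, "fever_spike", patient_id = 2)
  out <- ward_step(w)
  expect_gt(out$charts[["2"]]$P_ct$env_sensors$temperature, 38)

  w2 <- inject_event(out$ward, "fire")
  out2 <- ward_step(w2)
  expect_true(out2$ward$env$fire ||
                any(out2$ward$events$kind == "fire"))

  expect_error(inject_event(w, "meteorite"), "unknown event kind")
  expect_error(inject_event(w, "fever_spike", patient_id = 999),
               "unknown patient")
})

test_that("motor failure disables commanded tilt correction", {
  cfg <- tiny_config(seed = 9, rate_motor_failure = 0,
                     vitals_rates = list(tilt_drift = 1, mf_clear_alert = 0,
                                         mf_clear_spont = 0))
  w <- init_ward(cfg)
  w <- inject_event(w, "motor_failure", patient_id = 1)
  out <- ward_step(w)                       # tilt drifts unsafe
  expect_true(out$ward$lat[1, "mf"] == 2L)
  tilt_before <- out$ward$lat[1, "tilt"]
  out2 <- ward_step(out$ward, stats::setNames(list("adjust_tilt"), "1"))
  expect_gte(out2$ward$lat[1, "tilt"], tilt_before)  # correction refused
})

test_that("unknown patients error and illegal actions are logged, not applied", {
  w <- init_ward(tiny_config(seed = 3))
  expect_error(ward_step(w, stats::setNames(list("no_op"), "77")),
               "unknown patient")
  out <- ward_step(w, stats::setNames(list("sing_a_song"), "1"))
  expect_true(any(out$events$kind == "illegal_action"))
})

test_that("fall events require sustained unsafe tilt and are logged", {
  # force certain drift, disable the actuator, leave patients untreated
  cfg <- tiny_config(seed = 13, rate_motor_failure = 0,
                     vitals_rates = list(tilt_drift = 1))
  w <- init_ward(cfg)
  falls <- 0L
  for (k in 1:4) {
    out <- ward_step(w)
    w <- out$ward
    falls <- falls + sum(out$events$kind == "fall")
  }
  # drift at step 1, unsafe streak at steps 2,3 -> fall on the third unsafe step
  expect_gt(falls, 0)
  expect_true(all(w$events$step[w$events$kind == "fall"] >= 3))
})

test_that("observation noise and delay behave as specified", {
  ch <- synthetic_chart(heart_rate = 100)
  expect_identical(inject_noise(ch, 0, 0), ch)

  set.seed(1)
  hrs <- replicate(200, inject_noise(ch, 0.08, 0)$P_states$body_sensors$heart_rate)
  expect_true(all(abs(hrs - 100) <= 8 + 1e-9))
  expect_gt(stats::sd(hrs), 0)

  hist <- list(synthetic_chart(heart_rate = 70),
               synthetic_chart(heart_rate = 80),
               synthetic_chart(heart_rate = 90))
  delayed <- inject_noise(hist[[3]], 0, 2, history = hist)
  expect_equal(delayed$P_states$body_sensors$heart_rate, 70)
  expect_error(inject_noise(ch, 0, -1), "non-negative")
  expect_error(inject_noise(ch, 2, 0), "noise_pct")
})
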