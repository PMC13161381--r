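# Discrete-time multi-agent ward simulator. Patients evolve on the shared
# clinical-regime kernel (dynamics.R); caregivers chase alerts on the grid;
# environmental controllers handle ward-level fire events. Deterministic
# under the configured seed: every subsystem draws from its own derived
# substream so ablations do not shift unrelated randomness.

sub_seed <- function(seed, stream, t = 0) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729 + t) %% 2147483629)
}

CONT_BOUNDS <- list(
  hr   = list(c(40, 59), c(60, 120), c(121, 180)),
  bp   = list(c(70, 89), c(90, 140), c(141, 200)),
  spo2 = list(c(80, 91.5), c(92, 100)),
  temp = list(c(36, 37.4), c(38.2, 40.5)),
  dis  = list(c(0, 25), c(26, 100))
)

tilt_bounds <- function(level, max_safe) {
  if (level == 1L) c(0, max_safe) else c(max_safe + 2, max_safe + 20)
}

emit_continuous <- function(lat, cfg) {
  n <- nrow(lat)
  cont <- matrix(0, n, 7L,
                 dimnames = list(NULL, c("hr", "bp", "spo2", "temp",
                                         "tilt", "emo", "sugar")))
  draw <- function(bounds) stats::runif(1, bounds[1], bounds[2])
  for (i in seq_len(n)) {
    cont[i, "hr"] <- draw(CONT_BOUNDS$hr[[lat[i, "hr"]]])
    cont[i, "bp"] <- draw(CONT_BOUNDS$bp[[lat[i, "bp"]]])
    cont[i, "spo2"] <- draw(CONT_BOUNDS$spo2[[lat[i, "spo2"]]])
    cont[i, "temp"] <- draw(CONT_BOUNDS$temp[[lat[i, "temp"]]])
    cont[i, "tilt"] <- draw(tilt_bounds(min(lat[i, "tilt"], 2L),
                                        cfg$max_safe_angle))
    cont[i, "emo"] <- draw(CONT_BOUNDS$dis[[lat[i, "dis"]]])
    cont[i, "sugar"] <- stats::runif(1, 80, 140)
  }
  cont
}

# Mean-reverting jitter within the current regime band; resample on band change.
update_continuous <- function(cont, lat_old, lat_new, cfg) {
  n <- nrow(cont)
  fields <- c(hr = "hr", bp = "bp", spo2 = "spo2", temp = "temp", dis = "emo")
  for (i in seq_len(n)) {
    for (f in names(fields)) {
      col <- fields[[f]]
      if (lat_new[i, f] != lat_old[i, f]) {
        cont[i, col] <- stats::runif(1, CONT_BOUNDS[[f]][[lat_new[i, f]]][1],
                                     CONT_BOUNDS[[f]][[lat_new[i, f]]][2])
      } else {
        b <- CONT_BOUNDS[[f]][[lat_new[i, f]]]
        mid <- mean(b)
        x <- cont[i, col] + 0.25 * (mid - cont[i, col]) +
          stats::rnorm(1, 0, 0.05 * (b[2] - b[1]))
        cont[i, col] <- min(max(x, b[1]), b[2])
      }
    }
    if (lat_new[i, "tilt"] != lat_old[i, "tilt"]) {
      cont[i, "tilt"] <- stats::runif(1,
        tilt_bounds(min(lat_new[i, "tilt"], 2L), cfg$max_safe_angle)[1],
        tilt_bounds(min(lat_new[i, "tilt"], 2L), cfg$max_safe_angle)[2])
    }
    cont[i, "sugar"] <- min(max(cont[i, "sugar"] + stats::rnorm(1, 0, 2),
                                70), 160)
  }
  cont
}

empty_events <- function() {
  tibble::tibble(step = integer(), kind = character(),
                 patient_id = integer(), payload = character())
}

#' Initialise a ward
#'
#' Places the configured patient, caregiver and environmental-controller
#' agents at distinct grid cells, assigns cerebral-palsy subtypes by
#' stratified rounding of the configured mix, and admits every patient in
#' the all-nominal clinical regime. Identical configurations (including
#' seed) produce byte-identical ward states.
#'
#' @param config A [ward_config()].
#' @return A `ward_state`.
#' @export
init_ward <- function(config) {
  validate_ward_config(config)
  set.seed(sub_seed(config$seed, 0L))
  n <- config$n_patients
  n_agents <- n + config$n_caregivers + config$n_env_controllers
  cells <- sample.int(config$grid_width * config$grid_height, n_agents)
  xs <- (cells - 1L) %% config$grid_width + 1L
  ys <- (cells - 1L) %/% config$grid_width + 1L

  mix <- config$subtype_mix
  base <- floor(mix * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(mix * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  subtype <- rep(names(mix), times = base)

  lat <- matrix(rep(c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L), each = n), n, 8L,
                dimnames = list(NULL, names(LAT_LEVELS)))
  cont <- emit_continuous(lat, config)
  subtype_tags <- cp_subtypes()

  ward <- list(
    config = config,
    patients = tibble::tibble(
      id = seq_len(n), subtype = subtype, x = xs[seq_len(n)],
      y = ys[seq_len(n)], fallen = rep(FALSE, n)),
    lat = lat, cont = cont,
    history = lapply(subtype, function(s) {
      c(paste0(s, "=", subtype_tags[[s]]),
        if (s %in% c("S1", "S2")) "Spasticity" else
          if (s == "S3") "Ataxia" else "Dyskinesia")
    }),
    prescriptions = lapply(subtype, function(s) {
      c("P1=Physical therapy",
        if (s %in% c("S1", "S4")) "P2=Intrathecal baclofen")
    }),
    recent_actions = rep(list(character()), n),
    caregivers = tibble::tibble(
      id = n + seq_len(config$n_caregivers),
      x = xs[n + seq_len(config$n_caregivers)],
      y = ys[n + seq_len(config$n_caregivers)]),
    env_controllers = tibble::tibble(
      id = n + config$n_caregivers + seq_len(config$n_env_controllers),
      x = xs[n + config$n_caregivers + seq_len(config$n_env_controllers)],
      y = ys[n + config$n_caregivers + seq_len(config$n_env_controllers)]),
    env = list(light = stats::runif(1, 100, 500), fire = FALSE,
               fire_x = NA_integer_, fire_y = NA_integer_,
               fire_radius = 5L, fire_temp = 45),
    step = 0L,
    events = empty_events(),
    pending = list(),
    chart_history = list()
  )
  class(ward) <- "ward_state"
  ward
}

#' @export
print.ward_state <- function(x, ...) {
  cat(sprintf("<ward_state> step %d | %d patients, %d caregivers, %d env controllers | %d events logged\n",
              x$step, nrow(x$patients), nrow(x$caregivers),
              nrow(x$env_controllers), nrow(x$events)))
  invisible(x)
}

EVENT_KINDS <- c("fever_spike", "fire", "motor_failure", "distress")

#' Inject an adversarial event
#'
#' Queues an event that takes effect at the next [ward_step()]:
#' `fever_spike` pushes a patient into the febrile regime, `motor_failure`
#' disables that patient's tilt actuator until cleared, `distress` raises
#' the emotional score past its trigger, and `fire` ignites the ward at a
#' seeded cell.
#'
#' @param ward A `ward_state`.
#' @param kind One of `"fever_spike"`, `"fire"`, `"motor_failure"`,
#'   `"distress"`.
#' @param patient_id Target patient (defaults to patient 1 for
#'   patient-level kinds; ignored for `fire`).
#' @return The ward with the event queued.
#' @export
inject_event <- function(ward, kind, patient_id = NULL) {
  if (!kind %in% EVENT_KINDS) {
    stop("inject_event: unknown event kind '", kind, "'", call. = FALSE)
  }
  if (kind != "fire" && is.null(patient_id)) patient_id <- ward$patients$id[1]
  if (!is.null(patient_id) && !patient_id %in% ward$patients$id) {
    stop("inject_event: unknown patient id ", patient_id, call. = FALSE)
  }
  ward$pending <- c(ward$pending, list(list(kind = kind,
                                            patient_id = patient_id)))
  ward
}

apply_pending <- function(ward) {
  for (ev in ward$pending) {
    i <- if (!is.null(ev$patient_id)) match(ev$patient_id, ward$patients$id)
    if (ev$kind == "fever_spike") {
      ward$lat[i, "temp"] <- 2L
      ward$cont[i, "temp"] <- stats::runif(1, 38.2, 40.5)
    } else if (ev$kind == "motor_failure") {
      ward$lat[i, "mf"] <- 2L
    } else if (ev$kind == "distress") {
      ward$lat[i, "dis"] <- 2L
      ward$cont[i, "emo"] <- stats::runif(1, 26, 100)
    } else if (ev$kind == "fire") {
      ward$env$fire <- TRUE
      ward$env$fire_x <- sample.int(ward$config$grid_width, 1)
      ward$env$fire_y <- sample.int(ward$config$grid_height, 1)
    }
  }
  ward$pending <- list()
  ward
}

action_id <- function(a) {
  if (is.numeric(a)) {
    ai <- as.integer(a)
    if (is.na(ai) || ai < 1L || ai > N_ACT) return(NA_integer_)
    return(ai)
  }
  m <- match(a, ward_actions())
  if (is.na(m)) NA_integer_ else as.integer(m)
}

#' Advance the ward by one step
#'
#' Applies queued events, evolves every patient's clinical regime under the
#' submitted care actions, runs ward-level fire dynamics, moves caregivers
#' one greedy Manhattan step toward the highest-priority alert (falls
#' before motor failures before fevers before distress; ties to the lowest
#' patient id), updates continuous sensor emissions, and returns the
#' per-patient cognitive charts and step rewards plus the new event
#' records. Unknown patient ids in `actions` raise an error; unknown action
#' values are rejected and logged as `illegal_action` events (the patient
#' receives no-op).
#'
#' @param ward A `ward_state`.
#' @param actions Named vector/list mapping patient id to an action name or
#'   id; omitted patients receive `no_op`.
#' @return List with `ward`, `charts` (named list of cognitive charts,
#'   noise/delay applied per the configuration), `rewards` (named numeric)
#'   and `events` (tibble of this step's new events).
#' @export
ward_step <- function(ward, actions = NULL) {
  cfg <- ward$config
  n <- nrow(ward$patients)
  t <- ward$step + 1L
  new_events <- empty_events()
  log_event <- function(kind, pid, payload = "") {
    new_events <<- dplyr::bind_rows(new_events, tibble::tibble(
      step = t, kind = kind, patient_id = as.integer(pid %||% NA),
      payload = payload))
  }

  act <- rep(1L, n)
  if (!is.null(actions)) {
    ids <- as.integer(names(actions))
    if (anyNA(ids) || !all(ids %in% ward$patients$id)) {
      stop("ward_step: unknown patient id in actions", call. = FALSE)
    }
    for (k in seq_along(actions)) {
      ai <- action_id(actions[[k]])
      if (is.na(ai)) {
        log_event("illegal_action", ids[k], paste0("rejected: ", actions[[k]]))
      } else {
        act[match(ids[k], ward$patients$id)] <- ai
      }
    }
  }

  set.seed(sub_seed(cfg$seed, 1L, t))
  ward <- apply_pending(ward)
  U <- matrix(stats::runif(n * 8L), n, 8L)
  fire_u <- stats::runif(2)

  lat_old <- ward$lat
  res <- clin_step(lat_old, act, U, cfg)
  ward$lat <- res$states
  rewards <- res$reward

  # ward-level fire: ignition, exposure within the fire radius, extinction
  if (!ward$env$fire && fire_u[1] < cfg$rate_fire) {
    ward$env$fire <- TRUE
    ward$env$fire_x <- as.integer(ceiling(fire_u[2] * cfg$grid_width))
    ward$env$fire_y <- as.integer(ceiling(stats::runif(1) * cfg$grid_height))
    log_event("fire", NA, sprintf("ignited at (%d,%d)",
                                  ward$env$fire_x, ward$env$fire_y))
  } else if (ward$env$fire) {
    near <- pmax(abs(ward$patients$x - ward$env$fire_x),
                 abs(ward$patients$y - ward$env$fire_y)) <= ward$env$fire_radius
    rewards <- rewards + cfg$rewards$hazard * near
    p_out <- if (any(act == 7L)) 0.6 else 0.3
    if (stats::runif(1) < p_out) {
      ward$env$fire <- FALSE
      log_event("fire", NA, "extinguished by environmental controllers")
    }
  }

  ward$patients$fallen <- res$fall
  for (i in which(res$fall)) log_event("fall", ward$patients$id[i], "tilt unsafe 3 consecutive steps")
  for (i in which(res$fever_onset)) log_event("fever_spike", ward$patients$id[i], "")
  for (i in which(res$mf_onset)) log_event("motor_failure", ward$patients$id[i], "")
  for (i in which(res$distress_onset)) log_event("distress", ward$patients$id[i], "")
  for (i in which(res$braked)) log_event("reflex_override", ward$patients$id[i], "brake+alert during motor failure")

  # caregivers chase the highest-priority alert
  pri <- 4L * res$fall + 3L * (ward$lat[, "mf"] == 2L) +
    2L * (ward$lat[, "temp"] == 2L) + 1L * (ward$lat[, "dis"] == 2L)
  if (any(pri > 0)) {
    target <- which(pri == max(pri))[1]   # lowest patient id among ties
    tx <- ward$patients$x[target]; ty <- ward$patients$y[target]
    dx <- sign(tx - ward$caregivers$x); dy <- sign(ty - ward$caregivers$y)
    movex <- abs(tx - ward$caregivers$x) >= abs(ty - ward$caregivers$y)
    ward$caregivers$x <- ward$caregivers$x + dx * movex
    ward$caregivers$y <- ward$caregivers$y + dy * (!movex)
  }

  set.seed(sub_seed(cfg$seed, 2L, t))
  ward$cont <- update_continuous(ward$cont, lat_old, ward$lat, cfg)
  ward$env$light <- min(max(ward$env$light + stats::rnorm(1, 0, 5), 100), 500)

  for (i in seq_len(n)) {
    ward$recent_actions[[i]] <- utils::tail(
      c(ward$recent_actions[[i]], ward_actions()[act[i]]), 5L)
  }

  ward$step <- t
  ward$events <- dplyr::bind_rows(ward$events, new_events)

  raw_charts <- lapply(ward$patients$id, function(pid) build_chart(ward, pid))
  names(raw_charts) <- as.character(ward$patients$id)
  ward$chart_history <- c(ward$chart_history, list(raw_charts))
  keep <- max(1L, cfg$observation_delay_steps + 1L)
  if (length(ward$chart_history) > keep) {
    ward$chart_history <- utils::tail(ward$chart_history, keep)
  }

  charts <- raw_charts
  if (cfg$sensor_noise_pct > 0 || cfg$observation_delay_steps > 0) {
    set.seed(sub_seed(cfg$seed, 3L, t))
    charts <- lapply(names(raw_charts), function(pid) {
      hist_pid <- lapply(ward$chart_history, `[[`, pid)
      inject_noise(raw_charts[[pid]], cfg$sensor_noise_pct,
                   cfg$observation_delay_steps, history = hist_pid)
    })
    names(charts) <- names(raw_charts)
  }

  names(rewards) <- as.character(ward$patients$id)
  list(ward = ward, charts = charts, rewards = rewards, events = new_events)
}

#' Perturb and delay an observation
#'
#' Applies multiplicative uniform noise `U(-noise_pct, +noise_pct)` to every
#' continuous sensor field of a cognitive chart (booleans and labels are
#' untouched) and, when `delay_steps > 0`, returns the chart recorded
#' `delay_steps` steps earlier from `history` (oldest available if the
#' buffer is shorter). Draws come from the current RNG state; seed the
#' stream before calling for reproducibility.
#'
#' @param observation A cognitive chart.
#' @param noise_pct Noise fraction in `[0, 1]`.
#' @param delay_steps Non-negative whole-step delay.
#' @param history List of past charts (oldest first, current last) used to
#'   realise the delay.
#' @return The perturbed (possibly delayed) chart.
#' @export
inject_noise <- function(observation, noise_pct = 0, delay_steps = 0,
                         history = NULL) {
  if (delay_steps < 0) {
    stop("inject_noise: delay_steps must be non-negative", call. = FALSE)
  }
  if (noise_pct < 0 || noise_pct > 1) {
    stop("inject_noise: noise_pct must lie in [0, 1]", call. = FALSE)
  }
  chart <- observation
  if (delay_steps > 0 && !is.null(history) && length(history) > 0) {
    idx <- max(1L, length(history) - delay_steps)
    chart <- history[[idx]]
  }
  if (noise_pct > 0) {
    jitter <- function(x) x * (1 + stats::runif(1, -noise_pct, noise_pct))
    b <- chart$P_states$body_sensors
    chart$P_states$body_sensors <- list(
      heart_rate = jitter(b$heart_rate), oxygen = jitter(b$oxygen),
      blood_pressure = jitter(b$blood_pressure), sugar = jitter(b$sugar))
    chart$P_states$tilt_angle <- jitter(chart$P_states$tilt_angle)
    chart$P_states$emotional_score <- jitter(chart$P_states$emotional_score)
    chart$P_ct$env_sensors$temperature <-
      jitter(chart$P_ct$env_sensors$temperature)
    chart$P_ct$env_sensors$light <- jitter(chart$P_ct$env_sensors$light)
  }
  chart
}
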