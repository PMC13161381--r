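#' Care actions available to the agent
#'
#' The discrete action vocabulary of the ward MDP, in fixed id order
#' (ties in action selection always break toward the lowest id).
#' `give_p1` is a physical-therapy session (WHO guideline-style 45-minute
#' session), `give_p2` an intrathecal baclofen dose for severe spasticity,
#' `activate_cooling` the cooling protocol triggered for fever,
#' `raise_alert` a caregiver call (also clears motor failures and applies
#' the wheelchair brake while the tilt actuator is down).
#'
#' @return Character vector of the seven action names, in id order.
#' @export
ward_actions <- function() {
  c("no_op", "adjust_tilt", "reposition", "activate_cooling",
    "give_p1", "give_p2", "raise_alert")
}

#' Cerebral-palsy subtype labels with ICD-10 tags
#' @return Named character vector mapping subtype codes S1-S4 to ICD-10 tags.
#' @export
cp_subtypes <- function() {
  c(S1 = "G80.1 spastic quadriplegia",
    S2 = "G80.2 spastic diplegia",
    S3 = "G80.4 ataxic",
    S4 = "G80.3 dyskinetic")
}

default_vitals_rates <- function() {
  list(
    hr_up          = 0.010,  # tachycardia onset per step
    hr_up_fever    = 0.150,  # extra onset hazard while febrile
    hr_down_p2     = 0.800,  # resolution under baclofen
    hr_down_spont  = 0.100,
    hr_low         = 0.002,  # bradycardia onset
    hr_low_rec     = 0.300,
    bp_up          = 0.008,
    bp_down_p2     = 0.800,
    bp_down_spont  = 0.100,
    bp_low         = 0.002,
    bp_low_rec     = 0.300,
    spo2_drop      = 0.004,
    spo2_rec_alert = 0.800,  # caregiver supplies oxygen after an alert
    spo2_rec_spont = 0.050,
    fever_cool     = 0.900,  # cooling protocol resolves fever next step
    fever_spont    = 0.050,
    tilt_drift     = 0.050,  # spastic drift past the safe angle
    dis_rec_repo   = 0.850,  # repositioning resolves distress
    dis_rec_spont  = 0.100,
    due_arrive     = 0.040,  # a therapy session becomes due
    mf_clear_alert = 0.600,  # alerted caregiver repairs the actuator
    mf_clear_spont = 0.050
  )
}

default_rewards <- function() {
  list(
    fall       = -100,
    hazard     = -50,   # per step of fever (or fire) exposure
    discomfort = -1,    # per step of distress / unsafe tilt / low SpO2
    comfort    = 1,     # all vitals nominal, safe tilt, calm
    adherence  = 10,    # therapy session delivered while due
    cost = c(no_op = 0, adjust_tilt = -0.5, reposition = -1,
             activate_cooling = -1, give_p1 = -2, give_p2 = -5,
             raise_alert = -1)
  )
}

#' Ward simulation configuration
#'
#' Builds and validates the configuration of the simulated cerebral-palsy
#' ward: a `grid_width` x `grid_height` ward populated by patient, caregiver
#' and environmental-controller agents, with per-step event rates and the
#' safety threshold on wheelchair tilt. Defaults mirror the reference study
#' conditions (50x50 grid; 40 patients, 10 caregivers, 21 environmental
#' controllers; 500 training episodes; subtype mix 40/30/15/15) except for
#' the episode horizon, which defaults to a desk-scale 50 steps.
#'
#' @param grid_width,grid_height Ward grid size in cells.
#' @param n_patients,n_caregivers,n_env_controllers Agent counts.
#' @param episodes Training episodes per run.
#' @param steps_per_episode Steps per episode (episode horizon).
#' @param subtype_mix Proportions over CP subtypes S1-S4; must sum to 1.
#' @param rate_fever,rate_fire,rate_motor_failure,rate_distress Per-step
#'   event rates (fire is ward-level; the rest are per patient).
#' @param sensor_noise_pct Multiplicative observation noise fraction in
#'   `[0, 1]` applied to continuous sensor fields.
#' @param observation_delay_steps Observation delay in whole steps.
#' @param max_safe_angle Maximum safe wheelchair tilt, degrees.
#' @param fall_after_steps Consecutive unsafe-tilt steps before a fall (k).
#' @param vitals_rates Named list of per-step clinical transition rates;
#'   see `wardrl:::default_vitals_rates()` for the fields.
#' @param rewards Named list of step-reward components (fall, hazard,
#'   discomfort, comfort, adherence, per-action cost vector).
#' @param seed Integer root seed; all subsystem streams derive from it.
#' @return A validated `ward_config` object (list).
#' @examples
#' cfg <- ward_config(n_patients = 4, episodes = 2)
#' cfg$subtype_mix
#' @export
ward_config <- function(grid_width = 50, grid_height = 50,
                        n_patients = 40, n_caregivers = 10,
                        n_env_controllers = 21,
                        episodes = 500, steps_per_episode = 50,
                        subtype_mix = c(S1 = 0.40, S2 = 0.30,
                                        S3 = 0.15, S4 = 0.15),
                        rate_fever = 0.004, rate_fire = 0.0005,
                        rate_motor_failure = 0.002, rate_distress = 0.03,
                        sensor_noise_pct = 0, observation_delay_steps = 0,
                        max_safe_angle = 25, fall_after_steps = 3,
                        vitals_rates = default_vitals_rates(),
                        rewards = default_rewards(),
                        seed = 1L) {
  cfg <- list(
    grid_width = as.integer(grid_width), grid_height = as.integer(grid_height),
    n_patients = as.integer(n_patients),
    n_caregivers = as.integer(n_caregivers),
    n_env_controllers = as.integer(n_env_controllers),
    episodes = as.integer(episodes),
    steps_per_episode = as.integer(steps_per_episode),
    subtype_mix = subtype_mix,
    rate_fever = rate_fever, rate_fire = rate_fire,
    rate_motor_failure = rate_motor_failure, rate_distress = rate_distress,
    sensor_noise_pct = sensor_noise_pct,
    observation_delay_steps = as.integer(observation_delay_steps),
    max_safe_angle = max_safe_angle,
    fall_after_steps = as.integer(fall_after_steps),
    vitals_rates = utils::modifyList(default_vitals_rates(),
                                     as.list(vitals_rates)),
    rewards = utils::modifyList(default_rewards(), as.list(rewards)),
    seed = as.integer(seed)
  )
  class(cfg) <- "ward_config"
  validate_ward_config(cfg)
  cfg
}

validate_ward_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid ward configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  counts <- c("grid_width", "grid_height", "n_patients", "n_caregivers",
              "n_env_controllers", "episodes", "steps_per_episode")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0L) {
      stop_cfg(f, "must be a single strictly positive count")
    }
  }
  if (abs(sum(cfg$subtype_mix) - 1) > 1e-9) {
    stop_cfg("subtype_mix", "must sum to 1 (tolerance 1e-9)")
  }
  if (any(cfg$subtype_mix < 0)) stop_cfg("subtype_mix", "must be non-negative")
  n_agents <- cfg$n_patients + cfg$n_caregivers + cfg$n_env_controllers
  if (n_agents > cfg$grid_width * cfg$grid_height) {
    stop_cfg("grid_width", "grid too small to place all agents at distinct cells")
  }
  for (f in c("rate_fever", "rate_fire", "rate_motor_failure", "rate_distress")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_cfg(f, "must be a rate in [0, 1]")
  }
  if (cfg$sensor_noise_pct < 0 || cfg$sensor_noise_pct > 1) {
    stop_cfg("sensor_noise_pct", "must lie in [0, 1]")
  }
  if (cfg$observation_delay_steps < 0) {
    stop_cfg("observation_delay_steps", "must be non-negative")
  }
  if (cfg$max_safe_angle <= 0) stop_cfg("max_safe_angle", "must be positive")
  if (cfg$fall_after_steps < 1) stop_cfg("fall_after_steps", "must be >= 1")
  invisible(cfg)
}

#' Read a ward configuration from YAML or JSON
#'
#' The document's top-level keys mirror the `ward_config()` argument names
#' exactly; unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `ward_config` object.
#' @export
read_ward_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(ward_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$subtype_mix)) raw$subtype_mix <- unlist(raw$subtype_mix)
  do.call(ward_config, raw)
}

#' @export
print.ward_config <- function(x, ...) {
  cat("<ward_config>\n")
  cat(sprintf("  grid %dx%d | %d patients, %d caregivers, %d env controllers\n",
              x$grid_width, x$grid_height, x$n_patients, x$n_caregivers,
              x$n_env_controllers))
  cat(sprintf("  %d episodes x %d steps | max safe tilt %g deg (fall after %d)\n",
              x$episodes, x$steps_per_episode, x$max_safe_angle,
              x$fall_after_steps))
  cat(sprintf("  rates: fever %g, fire %g, motor failure %g, distress %g\n",
              x$rate_fever, x$rate_fire, x$rate_motor_failure, x$rate_distress))
  cat(sprintf("  noise %g%%, delay %d steps, seed %d\n",
              100 * x$sensor_noise_pct, x$observation_delay_steps, x$seed))
  invisible(x)
}
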