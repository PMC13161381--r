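# The cognitive chart, its discretisation into the tabular state space, and
# the symbolic clinical rule layer.

#' Build the cognitive chart for a patient
#'
#' The per-patient observation record joining medical history (`X_tm`), the
#' current care intention (`X_ti`), record features (`X_tr`: active
#' prescriptions and the recent action window), patient context (`P_ct`:
#' environmental sensors, posture and facial flags) and current
#' physiological state (`P_states`: body sensors, tilt, emotional score).
#' Pure: identical ward states produce identical charts.
#'
#' @param ward A ward state from [init_ward()] / [ward_step()].
#' @param patient_id Patient id.
#' @return A `cognitive_chart`.
#' @export
build_chart <- function(ward, patient_id) {
  i <- match(patient_id, ward$patients$id)
  if (is.na(i)) {
    stop("build_chart: unknown patient id ", patient_id, call. = FALSE)
  }
  p <- ward$patients
  lat <- ward$lat[i, ]
  fire_near <- isTRUE(ward$env$fire) &&
    max(abs(c(p$x[i] - ward$env$fire_x, p$y[i] - ward$env$fire_y))) <=
      ward$env$fire_radius
  local_temp <- if (fire_near) ward$env$fire_temp else ward$cont[i, "temp"]
  chart <- list(
    patient_id = patient_id,
    step = ward$step,
    X_tm = ward$history[[i]],
    X_ti = if (lat["due"] == 2L) "deliver_therapy"
           else if (lat["dis"] == 2L) "comfort_patient" else "routine_care",
    X_tr = list(prescriptions = ward$prescriptions[[i]],
                recent_actions = ward$recent_actions[[i]]),
    P_ct = list(
      env_sensors = list(light = ward$env$light, fire = fire_near,
                         temperature = local_temp, smoke = fire_near),
      posture = list(DP_Wa = p$fallen[i], EP_Wa = FALSE,
                     UP_Wa = lat["tilt"] > 1L),
      facial_expression = if (lat["dis"] == 2L) "Crying" else "Neutral"
    ),
    P_states = list(
      body_sensors = list(heart_rate = ward$cont[i, "hr"],
                          oxygen = ward$cont[i, "spo2"],
                          blood_pressure = ward$cont[i, "bp"],
                          sugar = ward$cont[i, "sugar"]),
      tilt_angle = ward$cont[i, "tilt"],
      emotional_score = ward$cont[i, "emo"]
    )
  )
  class(chart) <- "cognitive_chart"
  chart
}

#' @export
print.cognitive_chart <- function(x, ...) {
  b <- x$P_states$body_sensors
  cat(sprintf(
    "<cognitive_chart> patient %s step %d | HR %.0f SpO2 %.0f BP %.0f T %.1f | tilt %.1f emo %.0f %s | intent %s\n",
    x$patient_id, x$step, b$heart_rate, b$oxygen, b$blood_pressure,
    x$P_ct$env_sensors$temperature, x$P_states$tilt_angle,
    x$P_states$emotional_score, x$P_ct$facial_expression, x$X_ti))
  invisible(x)
}

# Flat accessor for rule conditions.
chart_field <- function(chart, field) {
  switch(field,
    heart_rate = chart$P_states$body_sensors$heart_rate,
    oxygen = chart$P_states$body_sensors$oxygen,
    blood_pressure = chart$P_states$body_sensors$blood_pressure,
    sugar = chart$P_states$body_sensors$sugar,
    temperature = chart$P_ct$env_sensors$temperature,
    light = chart$P_ct$env_sensors$light,
    fire = chart$P_ct$env_sensors$fire,
    smoke = chart$P_ct$env_sensors$smoke,
    tilt_angle = chart$P_states$tilt_angle,
    emotional_score = chart$P_states$emotional_score,
    facial_expression = chart$P_ct$facial_expression,
    intention = chart$X_ti,
    stop("unknown chart field: ", field, call. = FALSE)
  )
}

#' Discretize a cognitive chart into the tabular state space
#'
#' Bins every continuous field at its clinical trigger threshold: heart rate
#' `{<60, 60-120, >120}` bpm, systolic blood pressure `{<90, 90-140, >140}`
#' mmHg, SpO2 `{<92, >=92}` %, temperature `{<38, >=38}` C, tilt
#' `{<=max_safe_angle, >}`, distress (emotional score `> 25` or a Crying
#' expression; the generator emits the two together, so they share a bin),
#' and therapy-due (from the care intention). The index is a bijective
#' mixed-radix encoding of the bin vector (288 states), stable across runs.
#'
#' @param chart A [build_chart()] result.
#' @param max_safe_angle Safe-tilt threshold in degrees.
#' @return A `discrete_state`: list with `index` and named `bin_vector`.
#' @export
discretize <- function(chart, max_safe_angle = 25) {
  b <- chart$P_states$body_sensors
  hr_v <- b$heart_rate
  if (hr_v < 20 || hr_v > 250) {
    warning("heart rate ", hr_v, " outside simulation bounds; clipped to edge bin")
  }
  hr <- if (hr_v < 60) 1L else if (hr_v <= 120) 2L else 3L
  bp <- if (b$blood_pressure < 90) 1L else if (b$blood_pressure <= 140) 2L else 3L
  spo2 <- if (b$oxygen < 92) 1L else 2L
  temp <- if (chart$P_ct$env_sensors$temperature >= 38) 2L else 1L
  tiltb <- if (chart$P_states$tilt_angle > max_safe_angle) 2L else 1L
  dis <- if (chart$P_states$emotional_score > 25 ||
               identical(chart$P_ct$facial_expression, "Crying")) 2L else 1L
  due <- if (identical(chart$X_ti, "deliver_therapy")) 2L else 1L
  bins <- c(hr = hr, bp = bp, spo2 = spo2, temp = temp, tilt = tiltb,
            distress = dis, therapy_due = due)
  structure(list(index = obs_pack(hr, bp, spo2, temp, tiltb, dis, due),
                 bin_vector = bins),
            class = "discrete_state")
}

#' Number of discrete observation states
#' @return 288, the size of the binned state space.
#' @export
n_discrete_states <- function() N_OBS

#' Default symbolic clinical rule set
#'
#' Threshold rules carrying their clinical provenance: tachycardia
#' (HR > 120 bpm, ICD-10 R00.0), hypertension (systolic > 140 mmHg),
#' hypoxemia (SpO2 < 92%), fever forcing the cooling protocol
#' (temperature > 38 C), distress and crying tags, and the unsafe-tilt tag.
#' Rules are applied in rule-id order; force beats mask beats tag.
#'
#' @param max_safe_angle Safe-tilt threshold for the posture rule.
#' @return A tibble of `symbolic_rule` rows: id, field, op, value, effect,
#'   action, label, amount, provenance.
#' @export
clinical_rules <- function(max_safe_angle = 25) {
  tibble::tribble(
    ~id,   ~field,             ~op,  ~value, ~effect,        ~action,            ~label,                          ~amount, ~provenance,
    "r01", "heart_rate",       ">",  120,    "tag",          NA,                 "S1 R00.0 tachycardia",          NA,      "ICD-10 R00.0; WHO HEARTS",
    "r02", "blood_pressure",   ">",  140,    "tag",          NA,                 "I10 hypertension",              NA,      "WHO HEARTS threshold 140 mmHg",
    "r03", "temperature",      ">",  38,     "force_action", "activate_cooling", "cooling protocol",              NA,      "WHO housing guidance; fever response",
    "r04", "oxygen",           "<",  92,     "tag",          NA,                 "R09.02 hypoxemia",              NA,      "SpO2 < 92% desaturation",
    "r05", "emotional_score",  ">",  25,     "tag",          NA,                 "distress ES>25",                NA,      "emotional-score trigger",
    "r06", "facial_expression","==", NA,     "tag",          NA,                 "FP_Wa crying",                  NA,      "facial processing unit",
    "r07", "tilt_angle",       ">",  max_safe_angle, "tag",  NA,                 "unsafe tilt",                   NA,      "MAX_SAFE_ANGLE exceeded"
  )
}

rule_fires <- function(rule, chart) {
  v <- chart_field(chart, rule$field)
  ref <- if (rule$field == "facial_expression") "Crying" else rule$value
  switch(rule$op,
         ">"  = isTRUE(v > ref),
         ">=" = isTRUE(v >= ref),
         "<"  = isTRUE(v < ref),
         "<=" = isTRUE(v <= ref),
         "==" = identical(v, ref),
         stop("unknown rule operator: ", rule$op, call. = FALSE))
}

#' Apply symbolic rules to a chart
#'
#' Evaluates every rule against the chart and folds the fired effects:
#' tags accumulate, `mask_action` removes actions from the candidate set
#' (never emptying it: if everything is masked the no-op fallback remains),
#' `force_action` pins the action (two distinct forced actions raise an
#' error naming the rules), and `bonus` effects accumulate a per-action
#' shaping bonus (a bonus with no action applies to every candidate).
#'
#' @param rules Rule tibble as from [clinical_rules()].
#' @param chart A cognitive chart.
#' @param candidate_actions Non-empty character vector of action names.
#' @return List with `tags`, `allowed_actions`, `forced_action` (or `NULL`),
#'   `shaping_bonus` (named numeric over candidates) and `fired` (rule ids).
#' @export
apply_rules <- function(rules, chart, candidate_actions = ward_actions()) {
  if (length(candidate_actions) == 0L) {
    stop("apply_rules: candidate_actions must be non-empty", call. = FALSE)
  }
  tags <- character()
  fired <- character()
  allowed <- candidate_actions
  forced <- character()
  forced_by <- character()
  bonus <- stats::setNames(numeric(length(candidate_actions)),
                           candidate_actions)
  rules <- rules[order(rules$id), ]
  for (k in seq_len(nrow(rules))) {
    rule <- rules[k, ]
    if (!rule_fires(rule, chart)) next
    fired <- c(fired, rule$id)
    if (rule$effect == "tag") {
      tags <- c(tags, rule$label)
    } else if (rule$effect == "mask_action") {
      allowed <- setdiff(allowed, rule$action)
    } else if (rule$effect == "force_action") {
      forced <- c(forced, rule$action)
      forced_by <- c(forced_by, rule$id)
    } else if (rule$effect == "bonus") {
      if (is.na(rule$action)) {
        bonus <- bonus + rule$amount
      } else if (rule$action %in% names(bonus)) {
        bonus[rule$action] <- bonus[rule$action] + rule$amount
      }
    } else {
      stop("unknown rule effect: ", rule$effect, call. = FALSE)
    }
  }
  forced_u <- unique(forced)
  if (length(forced_u) > 1L) {
    stop("conflicting force_action rules: ", paste(forced_by, collapse = ", "),
         call. = FALSE)
  }
  if (length(allowed) == 0L) allowed <- "no_op"
  list(tags = tags, allowed_actions = allowed,
       forced_action = if (length(forced_u)) forced_u else NULL,
       shaping_bonus = bonus, fired = fired)
}
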