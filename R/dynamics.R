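# Clinical-regime dynamics shared by the care-loop MDP and the ward simulator.
#
# Each patient carries a latent regime vector of eight clinical factors:
#   hr   1=low 2=normal 3=high        (bradycardia / nominal / tachycardia)
#   bp   1=low 2=normal 3=high        (systolic)
#   spo2 1=low 2=normal
#   temp 1=normal 2=fever             (> 38 C)
#   tilt 1=safe 2=unsafe(1) 3=unsafe(2)  unsafe-streak; 3rd unsafe step falls
#   dis  1=calm 2=distress            (emotional score > 25, crying)
#   due  1=no 2=therapy session due
#   mf   1=intact 2=motor failure     (tilt actuator down; latent, unobserved)
# Transitions factorise given (state, action), so the exact kernel is the
# row-wise Kronecker product of the per-factor distributions. The same
# per-factor draws drive simulation, which makes the kernel an exact
# description (not an approximation) of the simulated process.

LAT_LEVELS <- c(hr = 3L, bp = 3L, spo2 = 2L, temp = 2L, tilt = 3L,
                dis = 2L, due = 2L, mf = 2L)
N_LAT <- 864L   # prod(LAT_LEVELS)
N_OBS <- 288L   # observed regimes: tilt collapsed to safe/unsafe, mf hidden
N_ACT <- 7L

lat_pack <- function(m) {
  # m: integer matrix n x 8 (columns in LAT_LEVELS order) -> index 1..864
  radix <- cumprod(c(1L, LAT_LEVELS[-length(LAT_LEVELS)]))
  as.integer(1L + (m - 1L) %*% radix)
}

lat_unpack <- function(idx) {
  idx <- as.integer(idx) - 1L
  out <- matrix(0L, length(idx), length(LAT_LEVELS),
                dimnames = list(NULL, names(LAT_LEVELS)))
  for (f in seq_along(LAT_LEVELS)) {
    out[, f] <- idx %% LAT_LEVELS[f] + 1L
    idx <- idx %/% LAT_LEVELS[f]
  }
  out
}

# Observed discrete state: (hr, bp, spo2, temp, tilt>safe, dis, due), 288 states.
obs_pack <- function(hr, bp, spo2, temp, tiltb, dis, due) {
  as.integer(hr + 3L * (bp - 1L) + 9L * (spo2 - 1L) + 18L * (temp - 1L) +
               36L * (tiltb - 1L) + 72L * (dis - 1L) + 144L * (due - 1L))
}

lat_to_obs_map <- function() {
  m <- lat_unpack(seq_len(N_LAT))
  obs_pack(m[, "hr"], m[, "bp"], m[, "spo2"], m[, "temp"],
           1L + (m[, "tilt"] > 1L), m[, "dis"], m[, "due"])
}

lat_start <- function() {
  # all-nominal admission state
  lat_pack(matrix(c(2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L), 1L))
}

# One simulation step for n patients at once.
# states: n x 8 integer matrix; actions: integer vector (1..7); U: n x 8
# uniforms (one channel per factor). Returns new states, per-patient reward
# and event flags. Action ids follow ward_actions().
clin_step <- function(states, actions, U, cfg) {
  r <- cfg$vitals_rates
  rw <- cfg$rewards
  hr <- states[, 1L]; bp <- states[, 2L]; spo2 <- states[, 3L]
  temp <- states[, 4L]; tilt <- states[, 5L]; dis <- states[, 6L]
  due <- states[, 7L]; mf <- states[, 8L]
  a_adj <- actions == 2L; a_repo <- actions == 3L; a_cool <- actions == 4L
  a_p1 <- actions == 5L; a_p2 <- actions == 6L; a_alert <- actions == 7L

  up_p <- r$hr_up + r$hr_up_fever * (temp == 2L)
  down_p <- ifelse(a_p2, r$hr_down_p2, r$hr_down_spont)
  hr2 <- ifelse(hr == 3L, ifelse(U[, 1L] < down_p, 2L, 3L),
         ifelse(hr == 1L, ifelse(U[, 1L] < r$hr_low_rec, 2L, 1L),
                ifelse(U[, 1L] < up_p, 3L,
                       ifelse(U[, 1L] > 1 - r$hr_low, 1L, 2L))))

  bdown <- ifelse(a_p2, r$bp_down_p2, r$bp_down_spont)
  bp2 <- ifelse(bp == 3L, ifelse(U[, 2L] < bdown, 2L, 3L),
         ifelse(bp == 1L, ifelse(U[, 2L] < r$bp_low_rec, 2L, 1L),
                ifelse(U[, 2L] < r$bp_up, 3L,
                       ifelse(U[, 2L] > 1 - r$bp_low, 1L, 2L))))

  srec <- ifelse(a_alert, r$spo2_rec_alert, r$spo2_rec_spont)
  spo22 <- ifelse(spo2 == 1L, ifelse(U[, 3L] < srec, 2L, 1L),
                  ifelse(U[, 3L] < r$spo2_drop, 1L, 2L))

  tcool <- ifelse(a_cool, r$fever_cool, r$fever_spont)
  temp2 <- ifelse(temp == 2L, ifelse(U[, 4L] < tcool, 1L, 2L),
                  ifelse(U[, 4L] < cfg$rate_fever, 2L, 1L))

  mf_on <- mf == 2L
  corrected <- a_adj & !mf_on
  braked <- a_alert & mf_on
  fall <- tilt == 3L & !corrected & !braked
  tilt2 <- ifelse(corrected, 1L,
           ifelse(braked, tilt,
           ifelse(tilt == 1L, ifelse(U[, 5L] < r$tilt_drift, 2L, 1L),
                  ifelse(tilt == 2L, 3L, 1L))))

  drec <- ifelse(a_repo, r$dis_rec_repo, r$dis_rec_spont)
  dis2 <- ifelse(dis == 2L, ifelse(U[, 6L] < drec, 1L, 2L),
                 ifelse(U[, 6L] < cfg$rate_distress, 2L, 1L))

  due2 <- ifelse(due == 2L, ifelse(a_p1, 1L, 2L),
                 ifelse(U[, 7L] < r$due_arrive, 2L, 1L))

  mfclr <- ifelse(a_alert, r$mf_clear_alert, r$mf_clear_spont)
  mf2 <- ifelse(mf == 2L, ifelse(U[, 8L] < mfclr, 1L, 2L),
                ifelse(U[, 8L] < cfg$rate_motor_failure, 2L, 1L))

  nominal <- hr2 == 2L & bp2 == 2L & spo22 == 2L & temp2 == 1L &
    tilt2 == 1L & dis2 == 1L
  reward <- unname(rw$cost[actions]) +
    rw$adherence * (a_p1 & due == 2L) +
    rw$fall * fall +
    rw$hazard * (temp2 == 2L) +
    rw$discomfort * ((dis2 == 2L) + (tilt2 > 1L) + (spo22 == 1L)) +
    rw$comfort * nominal

  new <- cbind(hr2, bp2, spo22, temp2, tilt2, dis2, due2, mf2)
  colnames(new) <- names(LAT_LEVELS)
  list(states = new, reward = as.numeric(reward), fall = fall,
       fever_onset = temp == 1L & temp2 == 2L,
       mf_onset = mf == 1L & mf2 == 2L,
       distress_onset = dis == 1L & dis2 == 2L,
       braked = braked)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-factor next-state distribution matrices for every (state, action) pair,
# used to assemble the exact kernel. Returns list over factors of
# [N_LAT * N_ACT, levels_f] matrices; rows ordered state-fastest.
factor_dists <- function(cfg) {
  r <- cfg$vitals_rates
  g <- lat_unpack(rep(seq_len(N_LAT), times = N_ACT))
  a <- rep(seq_len(N_ACT), each = N_LAT)
  a_adj <- a == 2L; a_repo <- a == 3L; a_cool <- a == 4L
  a_p1 <- a == 5L; a_p2 <- a == 6L; a_alert <- a == 7L
  hr <- g[, "hr"]; bp <- g[, "bp"]; spo2 <- g[, "spo2"]; temp <- g[, "temp"]
  tilt <- g[, "tilt"]; dis <- g[, "dis"]; due <- g[, "due"]; mf <- g[, "mf"]
  n <- length(a)

  d_hr <- matrix(0, n, 3L)
  up_p <- r$hr_up + r$hr_up_fever * (temp == 2L)
  down_p <- ifelse(a_p2, r$hr_down_p2, r$hr_down_spont)
  i <- hr == 3L; d_hr[i, 2L] <- down_p[i]; d_hr[i, 3L] <- 1 - down_p[i]
  i <- hr == 1L; d_hr[i, 2L] <- r$hr_low_rec; d_hr[i, 1L] <- 1 - r$hr_low_rec
  i <- hr == 2L
  d_hr[i, 3L] <- up_p[i]; d_hr[i, 1L] <- r$hr_low
  d_hr[i, 2L] <- 1 - up_p[i] - r$hr_low

  d_bp <- matrix(0, n, 3L)
  bdown <- ifelse(a_p2, r$bp_down_p2, r$bp_down_spont)
  i <- bp == 3L; d_bp[i, 2L] <- bdown[i]; d_bp[i, 3L] <- 1 - bdown[i]
  i <- bp == 1L; d_bp[i, 2L] <- r$bp_low_rec; d_bp[i, 1L] <- 1 - r$bp_low_rec
  i <- bp == 2L
  d_bp[i, 3L] <- r$bp_up; d_bp[i, 1L] <- r$bp_low
  d_bp[i, 2L] <- 1 - r$bp_up - r$bp_low

  d_sp <- matrix(0, n, 2L)
  srec <- ifelse(a_alert, r$spo2_rec_alert, r$spo2_rec_spont)
  i <- spo2 == 1L; d_sp[i, 2L] <- srec[i]; d_sp[i, 1L] <- 1 - srec[i]
  i <- spo2 == 2L; d_sp[i, 1L] <- r$spo2_drop; d_sp[i, 2L] <- 1 - r$spo2_drop

  d_tm <- matrix(0, n, 2L)
  tcool <- ifelse(a_cool, r$fever_cool, r$fever_spont)
  i <- temp == 2L; d_tm[i, 1L] <- tcool[i]; d_tm[i, 2L] <- 1 - tcool[i]
  i <- temp == 1L
  d_tm[i, 2L] <- cfg$rate_fever; d_tm[i, 1L] <- 1 - cfg$rate_fever

  d_ti <- matrix(0, n, 3L)
  mf_on <- mf == 2L
  corrected <- a_adj & !mf_on
  braked <- a_alert & mf_on
  d_ti[corrected, 1L] <- 1
  d_ti[braked, ] <- 0
  for (l in 1:3) d_ti[braked & tilt == l, l] <- 1
  free <- !corrected & !braked
  i <- free & tilt == 1L
  d_ti[i, 2L] <- r$tilt_drift; d_ti[i, 1L] <- 1 - r$tilt_drift
  d_ti[free & tilt == 2L, 3L] <- 1
  d_ti[free & tilt == 3L, 1L] <- 1   # fall step: penalty paid, tilt reset

  d_di <- matrix(0, n, 2L)
  drec <- ifelse(a_repo, r$dis_rec_repo, r$dis_rec_spont)
  i <- dis == 2L; d_di[i, 1L] <- drec[i]; d_di[i, 2L] <- 1 - drec[i]
  i <- dis == 1L
  d_di[i, 2L] <- cfg$rate_distress; d_di[i, 1L] <- 1 - cfg$rate_distress

  d_du <- matrix(0, n, 2L)
  i <- due == 2L
  d_du[i & a_p1, 1L] <- 1; d_du[i & !a_p1, 2L] <- 1
  i <- due == 1L
  d_du[i, 2L] <- r$due_arrive; d_du[i, 1L] <- 1 - r$due_arrive

  d_mf <- matrix(0, n, 2L)
  mfclr <- ifelse(a_alert, r$mf_clear_alert, r$mf_clear_spont)
  i <- mf == 2L; d_mf[i, 1L] <- mfclr[i]; d_mf[i, 2L] <- 1 - mfclr[i]
  i <- mf == 1L
  d_mf[i, 2L] <- cfg$rate_motor_failure
  d_mf[i, 1L] <- 1 - cfg$rate_motor_failure

  list(hr = d_hr, bp = d_bp, spo2 = d_sp, temp = d_tm, tilt = d_ti,
       dis = d_di, due = d_du, mf = d_mf)
}

#' True care-loop MDP (evaluation backdoor)
#'
#' Assembles the exact transition kernel and expected step rewards of the
#' per-patient care loop implied by a ward configuration. This is the
#' evaluation-only backdoor used to compute optimal returns by dynamic
#' programming; agents never see it.
#'
#' @param cfg A [ward_config()].
#' @return A `tabular_mdp`: list with `P` (list of `n_states x n_states`
#'   transition matrices, one per action), `R` (`n_states x n_actions`
#'   expected rewards), `start` (start-state index), `n_states`,
#'   `n_actions`, `actions`, and `obs_map` (latent-to-observed state map).
#' @export
care_mdp <- function(cfg) {
  fd <- factor_dists(cfg)
  n <- N_LAT * N_ACT
  # row-wise Kronecker compose, hr fastest (matches lat_pack radix)
  P <- matrix(1, n, 1L)
  for (d in fd) {
    lf <- ncol(d)
    nc <- ncol(P)
    P <- P[, rep(seq_len(nc), times = lf), drop = FALSE] *
      d[, rep(seq_len(lf), each = nc), drop = FALSE]
  }

  g <- lat_unpack(rep(seq_len(N_LAT), times = N_ACT))
  a <- rep(seq_len(N_ACT), each = N_LAT)
  rw <- cfg$rewards
  fall_p <- as.numeric(g[, "tilt"] == 3L &
                         !(a == 2L & g[, "mf"] == 1L) &
                         !(a == 7L & g[, "mf"] == 2L))
  p_fever2 <- fd$temp[, 2L]
  p_dis2 <- fd$dis[, 2L]
  p_tilt_un <- fd$tilt[, 2L] + fd$tilt[, 3L]
  p_sp_low <- fd$spo2[, 1L]
  p_nominal <- fd$hr[, 2L] * fd$bp[, 2L] * fd$spo2[, 2L] * fd$temp[, 1L] *
    fd$tilt[, 1L] * fd$dis[, 1L]
  r_sa <- unname(rw$cost[a]) +
    rw$adherence * (a == 5L & g[, "due"] == 2L) +
    rw$fall * fall_p +
    rw$hazard * p_fever2 +
    rw$discomfort * (p_dis2 + p_tilt_un + p_sp_low) +
    rw$comfort * p_nominal

  Plist <- lapply(seq_len(N_ACT), function(ai) {
    P[(ai - 1L) * N_LAT + seq_len(N_LAT), , drop = FALSE]
  })
  structure(list(P = Plist,
                 R = matrix(r_sa, N_LAT, N_ACT),
                 start = lat_start(),
                 n_states = N_LAT, n_actions = N_ACT,
                 actions = ward_actions(),
                 obs_map = lat_to_obs_map()),
            class = "tabular_mdp")
}

#' @export
print.tabular_mdp <- function(x, ...) {
  cat(sprintf("<tabular_mdp> %d states, %d actions\n",
              x$n_states, x$n_actions))
  invisible(x)
}
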