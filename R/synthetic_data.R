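# run code with a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the standing-start gait simulator
#'
#' Defaults describe an average middle-aged adult walking at free speed:
#' cadence ~1.9 steps/s, step length 0.65 m, swing phase 38% of the gait
#' cycle. Amplitudes are in meters (heights, sways) or degrees (ROMs);
#' `noise_sd` is the per-coordinate additive landmark noise, defaulting to
#' 0.5% of stature, the scale of marker jitter of video pose engines.
#'
#' @param stature Height (m).
#' @param cadence Steps per second.
#' @param step_length Forward distance gained per step at cruise (m).
#' @param swing_fraction Swing time as a fraction of the gait cycle, in
#'   (0.2, 0.8).
#' @param hip_rom_amp,knee_rom_amp Joint excursion amplitudes (deg).
#' @param heel_lift_amp,toe_clearance_amp Swing-phase lift of heel / toe (m).
#' @param head_sway_amp,trunk_sway_amp Lateral oscillation amplitudes (m).
#' @param vertical_bob_amp Vertical pelvis oscillation amplitude (m).
#' @param trunk_tilt_mean Mean forward trunk lean (deg).
#' @param onset_time Time of gait initiation (s); the walker stands still
#'   before it.
#' @param ramp_steps Steps over which step length ramps up to cruise.
#' @param noise_sd Landmark noise sd (m); `NULL` means `0.005 * stature`.
#' @param fps Frame rate (Hz), >= 20.
#' @return A validated `gait_params` list.
#' @export
gait_params <- function(stature = 1.65, cadence = 1.875, step_length = 0.65,
                        swing_fraction = 0.38, hip_rom_amp = 40,
                        knee_rom_amp = 55, heel_lift_amp = 0.10,
                        toe_clearance_amp = 0.05, head_sway_amp = 0.02,
                        trunk_sway_amp = 0.03, vertical_bob_amp = 0.02,
                        trunk_tilt_mean = 5, onset_time = 1.0, ramp_steps = 2,
                        noise_sd = NULL, fps = 30) {
  if (is.null(noise_sd)) noise_sd <- 0.005 * stature
  p <- list(stature = stature, cadence = cadence, step_length = step_length,
            swing_fraction = swing_fraction, hip_rom_amp = hip_rom_amp,
            knee_rom_amp = knee_rom_amp, heel_lift_amp = heel_lift_amp,
            toe_clearance_amp = toe_clearance_amp,
            head_sway_amp = head_sway_amp, trunk_sway_amp = trunk_sway_amp,
            vertical_bob_amp = vertical_bob_amp,
            trunk_tilt_mean = trunk_tilt_mean, onset_time = onset_time,
            ramp_steps = ramp_steps, noise_sd = noise_sd, fps = fps)
  amps <- c("hip_rom_amp", "knee_rom_amp", "heel_lift_amp",
            "toe_clearance_amp", "head_sway_amp", "trunk_sway_amp",
            "vertical_bob_amp", "noise_sd")
  for (a in amps) if (p[[a]] < 0) stop(a, " must be >= 0")
  if (p$swing_fraction <= 0.2 || p$swing_fraction >= 0.8)
    stop("swing_fraction must lie in (0.2, 0.8)")
  if (p$fps < 20) stop("fps must be >= 20")
  if (p$stature <= 0.5 || p$stature >= 2.5) stop("stature out of range")
  if (p$cadence <= 0 || p$step_length <= 0) stop("cadence and step_length must be > 0")
  structure(p, class = "gait_params")
}

# smoothstep, C1 at both ends
.sstep <- function(u) u * u * (3 - 2 * u)

#' Simulate a standing-start walk
#'
#' Generates a pose-landmark sequence for a walker who stands still, starts
#' at `onset_time`, and takes `n_steps` alternating steps (left foot leads).
#' Foot trajectories are prescribed analytically - the stance foot is
#' planted, the swing ankle rises as `sin(pi*u)` over the swing - so ground
#' truth contact events are exact; each knee is placed so that the internal
#' hip-knee-ankle angle follows the programmed flexion trajectory (constant
#' baseline in stance plus a `knee_rom_amp` pulse in swing), making the
#' programmed knee ROM exactly recoverable. Pelvis, trunk, head and arms
#' carry the programmed sway, bob, lean and arm-swing oscillations. i.i.d.
#' Gaussian noise of sd `noise_sd` is added to every landmark coordinate
#' after heel/toe heights are clipped at ground level.
#'
#' @param params A [gait_params()] object.
#' @param n_steps Number of steps (>= 5 so three full cycles close).
#' @param seed RNG seed for the landmark noise (restored afterwards).
#' @param meta Optional [trial_meta()] attached to the sequence.
#' @return List with `sequence` (a `pose_sequence`) and `truth` (onset time,
#'   exact event table, per-step cycle duration and swing fraction,
#'   programmed feature values).
#' @export
simulate_walk <- function(params = gait_params(), n_steps = 6L, seed = NULL,
                          meta = NULL) {
  stopifnot(inherits(params, "gait_params"))
  if (n_steps < 5L)
    stop("n_steps must be >= 5 so that all three step cycles can close")
  p <- params
  H <- p$stature
  T_step <- 1 / p$cadence
  cyc <- 2 * T_step
  T_sw <- p$swing_fraction * cyc
  onset <- p$onset_time
  strikes <- onset + seq_len(n_steps) * T_step
  sides <- rep(c("left", "right"), length.out = n_steps)
  toe_offs <- strikes - T_sw
  dur <- onset + n_steps * T_step + 0.8
  t <- seq(0, dur, by = 1 / p$fps)
  n <- length(t)

  # strike positions with a step-length ramp over ramp_steps
  rmp <- pmin(seq_len(n_steps) / max(1L, p$ramp_steps), 1)
  Z <- cumsum(p$step_length * rmp)

  a0 <- 0.039 * H      # ankle height
  h0 <- 0.010 * H      # heel height in stance
  t0y <- 0.004 * H     # toe height in stance
  foot_half <- 0.05 * H
  fx <- c(left = +0.05 * H, right = -0.05 * H)

  foot_traj <- function(side) {
    ks <- which(sides == side)
    z <- rep(0, n); yb <- rep(0, n)   # z position; swing bump phase sin(pi u)
    swing <- rep(FALSE, n)
    for (k in ks) {
      z_prev <- if (k <= 2) 0 else Z[k - 2L]
      i <- t >= toe_offs[k] & t < strikes[k]
      u <- (t[i] - toe_offs[k]) / T_sw
      z[i] <- z_prev + (Z[k] - z_prev) * .sstep(u)
      yb[i] <- sin(pi * u)
      swing[i] <- TRUE
      z[t >= strikes[k]] <- Z[k]
    }
    list(z = z, bump = yb, swing = swing)
  }
  fl <- foot_traj("left")
  fr <- foot_traj("right")

  f_str <- p$cadence / 2                      # stride frequency
  t_w0 <- toe_offs[1]
  w <- pmin(pmax((t - t_w0) / T_step, 0), 1) *
    pmin(pmax(1 - (t - strikes[n_steps]) / T_step, 0), 1)
  ph <- 2 * pi * f_str * (t - strikes[1])

  # pelvis
  pz <- (fl$z + fr$z) / 2
  py <- 0.530 * H + p$vertical_bob_amp * sin(2 * ph) * w
  px <- 0.5 * p$trunk_sway_amp * sin(ph) * w

  deg <- pi / 180
  obl <- 4 * deg * sin(ph) * w          # pelvic obliquity (frontal)
  rot <- 6 * deg * sin(ph + pi / 2) * w # pelvic rotation (transverse)
  pw <- 0.096 * H
  hip_off <- cbind(pw * cos(obl) * cos(rot), pw * sin(obl), -pw * cos(obl) * sin(rot))
  mid_hip <- cbind(px, py, pz)
  left_hip <- mid_hip + hip_off
  right_hip <- mid_hip - hip_off

  # trunk: forward lean plus a hip-flexion-driven fore-aft rock
  tilt <- (p$trunk_tilt_mean + 0.05 * p$hip_rom_amp * sin(ph) * w) * deg
  trunk_len <- 0.288 * H
  shoulder_sway <- 1.5 * p$trunk_sway_amp * sin(ph) * w
  mid_shoulder <- cbind(shoulder_sway,
                        py + trunk_len * cos(tilt),
                        pz + trunk_len * sin(tilt))
  sh_rot <- -0.5 * rot                  # shoulders counter-rotate
  sw_half <- 0.129 * H
  sh_off <- cbind(sw_half * cos(sh_rot), 0 * t, -sw_half * sin(sh_rot))
  left_shoulder <- mid_shoulder + sh_off
  right_shoulder <- mid_shoulder - sh_off

  # head on top of the trunk with its own lateral sway
  head_len <- 0.118 * H
  tilt_h <- 0.5 * tilt
  head_center <- cbind(mid_shoulder[, 1] + p$head_sway_amp * sin(ph + 0.4) * w,
                       mid_shoulder[, 2] + head_len * cos(tilt_h),
                       mid_shoulder[, 3] + head_len * sin(tilt_h))

  lm <- array(NA_real_, c(n, 33L, 3L),
              dimnames = list(NULL, landmark_names(), .axes))
  put <- function(name, m) lm[, name, ] <<- m
  put("left_hip", left_hip); put("right_hip", right_hip)
  put("left_shoulder", left_shoulder); put("right_shoulder", right_shoulder)

  put("nose", head_center + cbind(0 * t, 0.020 * H + 0 * t, 0.040 * H + 0 * t))
  put("left_ear", head_center + cbind(+0.045 * H + 0 * t, -0.010 * H + 0 * t, -0.020 * H + 0 * t))
  put("right_ear", head_center + cbind(-0.045 * H + 0 * t, -0.010 * H + 0 * t, -0.020 * H + 0 * t))
  eye_dx <- c(inner = 0.008, mid = 0.015, outer = 0.022) * H
  for (s in c("left", "right")) {
    sg <- if (s == "left") 1 else -1
    put(paste0(s, "_eye_inner"),
        head_center + cbind(sg * eye_dx[["inner"]] + 0 * t, 0.018 * H + 0 * t, 0.035 * H + 0 * t))
    put(paste0(s, "_eye"),
        head_center + cbind(sg * eye_dx[["mid"]] + 0 * t, 0.018 * H + 0 * t, 0.033 * H + 0 * t))
    put(paste0(s, "_eye_outer"),
        head_center + cbind(sg * eye_dx[["outer"]] + 0 * t, 0.018 * H + 0 * t, 0.030 * H + 0 * t))
    put(paste0("mouth_", s),
        head_center + cbind(sg * 0.012 * H + 0 * t, -0.012 * H + 0 * t, 0.036 * H + 0 * t))
  }

  # arms: pendulum antiphase to the same-side leg, slight elbow flexion
  ua <- 0.186 * H; fa <- 0.146 * H
  for (s in c("left", "right")) {
    phase <- if (s == "left") pi else 0
    alpha <- 15 * deg * sin(ph + phase) * w
    sh <- if (s == "left") left_shoulder else right_shoulder
    elbow <- sh + cbind(0 * t, -ua * cos(alpha), ua * sin(alpha))
    gam <- alpha + 25 * deg
    wrist <- elbow + cbind(0 * t, -fa * cos(gam), fa * sin(gam))
    put(paste0(s, "_elbow"), elbow)
    put(paste0(s, "_wrist"), wrist)
    put(paste0(s, "_pinky"), wrist + cbind(0 * t, -0.02 * H + 0 * t, 0.015 * H + 0 * t))
    put(paste0(s, "_index"), wrist + cbind(0 * t, -0.02 * H + 0 * t, 0.022 * H + 0 * t))
    put(paste0(s, "_thumb"), wrist + cbind(0 * t, -0.012 * H + 0 * t, 0.020 * H + 0 * t))
  }

  # legs: prescribed feet; knee placed for an exact internal angle
  flex0 <- 8 * deg
  # the ankle's swing excursion is anatomically fairly invariant (the shank
  # swings through regardless of how much heel clearance the walker keeps),
  # so it gets a floor plus a partial coupling to the programmed heel lift
  ankle_lift <- 0.05 + 0.7 * p$heel_lift_amp
  for (s in c("left", "right")) {
    ft <- if (s == "left") fl else fr
    ankle <- cbind(fx[[s]] + 0 * t, a0 + ankle_lift * ft$bump, ft$z)
    heel <- cbind(fx[[s]] + 0 * t, h0 + p$heel_lift_amp * ft$bump, ft$z - foot_half)
    toe <- cbind(fx[[s]] + 0 * t, t0y + p$toe_clearance_amp * ft$bump, ft$z + 2 * foot_half)
    heel[, 2] <- pmax(heel[, 2], 0)
    toe[, 2] <- pmax(toe[, 2], 0)
    hip <- if (s == "left") left_hip else right_hip
    flex <- flex0 + p$knee_rom_amp * deg * ft$bump
    kappa <- pi - flex                      # internal knee angle (rad)
    d <- sqrt(rowSums((ankle - hip)^2))
    u_ha <- (ankle - hip) / d
    # unit normal to the hip-ankle line, pointing forward: u_ha x x_axis
    nrm <- cbind(0 * t, u_ha[, 3], -u_ha[, 2])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    hoff <- (d / 2) / tan(kappa / 2)
    knee <- (hip + ankle) / 2 + nrm * hoff
    put(paste0(s, "_ankle"), ankle)
    put(paste0(s, "_heel"), heel)
    put(paste0(s, "_knee"), knee)
    put(paste0(s, "_foot_index"), toe)
  }

  if (p$noise_sd > 0)
    lm <- with_seed(seed, lm + stats::rnorm(length(lm), 0, p$noise_sd))

  events <- data.frame(
    side = c(sides, sides),
    kind = rep(c("heel_strike", "toe_off"), each = n_steps),
    time = c(strikes, toe_offs))
  events <- events[order(events$time), ]
  rownames(events) <- NULL

  truth <- list(
    onset = onset, events = events, sides = sides,
    strike_times = strikes, toe_off_times = toe_offs,
    cycle_duration = cyc, swing_fraction = p$swing_fraction,
    cadence = p$cadence,
    knee_rom = p$knee_rom_amp,
    # clearances above the stance baseline
    max_heel_height = p$heel_lift_amp,
    max_toe_clearance = p$toe_clearance_amp,
    strike_z = Z,
    walking_speed_by_step = c((Z[3] - Z[1]) / cyc,
                              (Z[4] - Z[2]) / cyc,
                              (Z[5] - Z[3]) / cyc)[seq_len(min(3L, n_steps - 2L))],
    params = p)

  list(sequence = pose_sequence(t, lm, p$fps, meta = meta), truth = truth)
}

#' Specification of a synthetic labelled gait cohort
#'
#' Describes a cohort of participants, each walking three trials, with a
#' fall-history prevalence and standardized parameter shifts (`d`, in units
#' of the between-participant sd) applied to fallers' gait parameters. The
#' default shape mirrors a training cohort of 190 participants at 12.1%
#' fall-history prevalence with roughly half men; default faller effects
#' lower knee excursion and heel lift and raise swing-phase ratio and trunk
#' sway. Effect sizes are synthetic test constructions chosen so programmed
#' group differences are recoverable; they are not empirical estimates.
#'
#' @param n Number of participants.
#' @param prevalence Fall-history prevalence in (0, 1).
#' @param male_fraction Fraction of men.
#' @param trials_per_participant Trials each participant walks (default 3).
#' @param faller_effects Named numeric vector of standardized shifts applied
#'   to fallers' per-participant gait parameters.
#' @param between_trial_frac Trial-to-trial parameter jitter, as a fraction
#'   of the between-participant sd.
#' @param cohort `"training"` or `"validation"` tag.
#' @param noise_sd Landmark noise; `NULL` = 0.5% of each walker's stature.
#' @param seed Cohort RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 190L, prevalence = 0.121, male_fraction = 0.489,
                        trials_per_participant = 3L,
                        faller_effects = c(knee_rom_amp = -0.8,
                                           heel_lift_amp = -0.8,
                                           swing_fraction = +0.5,
                                           trunk_sway_amp = +0.5),
                        between_trial_frac = 0.3,
                        cohort = c("training", "validation"),
                        noise_sd = NULL, seed = 1L) {
  cohort <- match.arg(cohort)
  stopifnot(prevalence > 0, prevalence < 1, n >= 2)
  if (n * prevalence < 1)
    warning("n * prevalence < 1: a draw may contain no positives")
  structure(list(n = as.integer(n), prevalence = prevalence,
                 male_fraction = male_fraction,
                 trials_per_participant = as.integer(trials_per_participant),
                 faller_effects = faller_effects,
                 between_trial_frac = between_trial_frac,
                 cohort = cohort, noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

# between-participant sds of the simulator parameters
.param_sd <- c(cadence = 0.15, step_length = 0.06, swing_fraction = 0.03,
               hip_rom_amp = 5, knee_rom_amp = 6, heel_lift_amp = 0.02,
               toe_clearance_amp = 0.012, head_sway_amp = 0.008,
               trunk_sway_amp = 0.010, vertical_bob_amp = 0.005,
               trunk_tilt_mean = 2)

#' Simulate a labelled cohort of pose-level walking trials
#'
#' Draws per-participant gait parameters around the [gait_params()] defaults
#' with realistic between-participant spread, shifts fallers' parameters by
#' the programmed standardized effects, and simulates
#' `trials_per_participant` walks per participant with between-trial jitter.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param n_steps Steps per trial (default 6).
#' @return List with `trials` (list of [simulate_walk()] results, each with
#'   metadata attached) and `participants` (data frame of id, sex, stature,
#'   label).
#' @export
simulate_cohort <- function(spec = cohort_spec(), n_steps = 6L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
    stature <- ifelse(sex == "male",
                      stats::rnorm(n, 1.71, 0.060),
                      stats::rnorm(n, 1.58, 0.055))
    stature <- pmin(pmax(stature, 1.40), 2.00)
    label <- as.integer(stats::runif(n) < spec$prevalence)
    ids <- sprintf("P%03d", seq_len(n))
    trials <- list()
    for (i in seq_len(n)) {
      base <- unclass(gait_params(stature = stature[i]))
      for (pn in names(.param_sd))
        base[[pn]] <- base[[pn]] + stats::rnorm(1, 0, .param_sd[[pn]])
      if (label[i] == 1L)
        for (pn in names(spec$faller_effects))
          base[[pn]] <- base[[pn]] + spec$faller_effects[[pn]] * .param_sd[[pn]]
      for (tr in seq_len(spec$trials_per_participant)) {
        pt <- base
        for (pn in names(.param_sd))
          pt[[pn]] <- pt[[pn]] + stats::rnorm(1, 0, spec$between_trial_frac * .param_sd[[pn]])
        pt$swing_fraction <- min(max(pt$swing_fraction, 0.25), 0.48)
        pt$cadence <- max(pt$cadence, 1.2)
        pt$heel_lift_amp <- max(pt$heel_lift_amp, 0.02)
        pt$toe_clearance_amp <- max(pt$toe_clearance_amp, 0.01)
        pt$knee_rom_amp <- max(pt$knee_rom_amp, 20)
        for (a in c("head_sway_amp", "trunk_sway_amp", "vertical_bob_amp"))
          pt[[a]] <- max(pt[[a]], 0)
        if (!is.null(spec$noise_sd)) pt$noise_sd <- spec$noise_sd
        gp <- do.call(gait_params, pt[setdiff(names(pt), "noise_sd")])
        gp$noise_sd <- if (is.null(spec$noise_sd)) 0.005 * pt$stature else spec$noise_sd
        meta <- trial_meta(ids[i], sex[i], stature[i], label[i],
                           trial_index = tr, cohort = spec$cohort)
        trials[[length(trials) + 1L]] <-
          simulate_walk(gp, n_steps = n_steps,
                        seed = sample.int(.Machine$integer.max, 1), meta = meta)
      }
    }
    list(trials = trials,
         participants = data.frame(participant_id = ids, sex = sex,
                                   stature_m = stature, fall_history = label))
  })
}

#' Simulate a feature-level labelled cohort
#'
#' Generates a trial-by-feature table directly: per-participant feature
#' means are standard normal, fallers are shifted by `d` on the informative
#' features, and each of the participant's trials adds within-participant
#' noise. This is the input scale of the model-development pipeline and is
#' used to test screening, undersampling and the combination search against
#' known ground truth without the cost of pose-level simulation.
#'
#' @param n Participants.
#' @param prevalence Fall-history prevalence.
#' @param n_features Number of candidate features.
#' @param n_informative How many features carry the effect (the first ones).
#' @param d Standardized faller shift on informative features
#'   (participant-level sd units).
#' @param trials_per_participant Rows per participant.
#' @param within_sd Within-participant (between-trial) noise sd.
#' @param seed RNG seed.
#' @return Data frame with `participant_id`, `fall_history`, `trial_index`
#'   and feature columns `f01..`; attribute `"informative"` names the
#'   informative columns.
#' @export
simulate_feature_cohort <- function(n = 190L, prevalence = 0.121,
                                    n_features = 10L, n_informative = 3L,
                                    d = 0.8, trials_per_participant = 3L,
                                    within_sd = 0.5, seed = 1L) {
  with_seed(seed, {
    label <- as.integer(stats::runif(n) < prevalence)
    if (sum(label) == 0L) label[sample.int(n, 1)] <- 1L  # keep both classes
    M <- matrix(stats::rnorm(n * n_features), n, n_features)
    fn <- sprintf("f%02d", seq_len(n_features))
    colnames(M) <- fn
    inf <- fn[seq_len(n_informative)]
    M[label == 1L, seq_len(n_informative)] <-
      M[label == 1L, seq_len(n_informative)] + d
    idx <- rep(seq_len(n), each = trials_per_participant)
    X <- M[idx, , drop = FALSE] +
      matrix(stats::rnorm(length(idx) * n_features, 0, within_sd),
             length(idx), n_features)
    out <- data.frame(participant_id = sprintf("P%03d", idx),
                      fall_history = label[idx],
                      trial_index = rep(seq_len(trials_per_participant), n))
    out <- cbind(out, as.data.frame(X))
    attr(out, "informative") <- inf
    out
  })
}
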