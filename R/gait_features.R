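#' The 77-entry gait feature catalogue
#'
#' One set of per-cycle recipes instantiated for steps 1-3. Per step the
#' categories count 3 speed/acceleration, 5 temporal, 7 distance/height
#' (6 at step 1, where stride length is undefined - there is no previous
#' same-side contact) and 11 angular features: 77 in total. Distances and
#' heights are normalized by stature, velocities by the square root of
#' stature, accelerations by stature; times, ratios and angles are reported
#' unnormalized.
#'
#' @return Data frame with one row per feature: `name`, `category`,
#'   `step_index`, `units`, `normalization`, `description`, and the column
#'   name `column` (`<name>_s<step>`) used in feature tables.
#' @export
feature_registry <- function() {
  base <- rbind(
    data.frame(name = "walking_speed", category = "speed_accel",
               units = "1/s", normalization = "by_sqrt_stature",
               description = "z-displacement of the cycle-side foot over the cycle / duration"),
    data.frame(name = "max_swing_velocity", category = "speed_accel",
               units = "1/s", normalization = "by_sqrt_stature",
               description = "peak forward velocity of the swing foot during swing"),
    data.frame(name = "peak_swing_acceleration", category = "speed_accel",
               units = "1/s^2", normalization = "by_stature",
               description = "peak forward acceleration of the swing foot during swing"),
    data.frame(name = "cycle_duration", category = "time", units = "s",
               normalization = "none", description = "same-side contact to contact"),
    data.frame(name = "swing_time", category = "time", units = "s",
               normalization = "none", description = "toe-off to cycle end"),
    data.frame(name = "stance_time", category = "time", units = "s",
               normalization = "none", description = "cycle start to toe-off"),
    data.frame(name = "swing_phase_ratio", category = "time", units = "",
               normalization = "none", description = "swing time / cycle duration"),
    data.frame(name = "double_support_time", category = "time", units = "s",
               normalization = "none", description = "total time both feet in stance within the cycle"),
    data.frame(name = "stride_length", category = "distance_height", units = "",
               normalization = "by_stature",
               description = "z between successive same-side heel positions at contact"),
    data.frame(name = "max_heel_height", category = "distance_height", units = "",
               normalization = "by_stature", description = "peak heel height above its stance baseline during swing"),
    data.frame(name = "max_toe_clearance", category = "distance_height", units = "",
               normalization = "by_stature", description = "peak toe height above its stance baseline during swing"),
    data.frame(name = "head_sway", category = "distance_height", units = "",
               normalization = "by_stature", description = "lateral (x) range of the head center over the cycle"),
    data.frame(name = "trunk_sway", category = "distance_height", units = "",
               normalization = "by_stature", description = "lateral (x) range of the trunk center over the cycle"),
    data.frame(name = "vertical_trunk_movement", category = "distance_height", units = "",
               normalization = "by_stature", description = "vertical (y) range of the trunk center over the cycle"),
    data.frame(name = "step_width", category = "distance_height", units = "",
               normalization = "by_stature", description = "|x| between the ankles at the opposite-side contact"),
    data.frame(name = "knee_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the internal knee angle (cycle side)"),
    data.frame(name = "hip_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the internal hip angle (mid-shoulder / hip / knee)"),
    data.frame(name = "ankle_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the internal ankle angle (knee / ankle / toe)"),
    data.frame(name = "head_angle_mean", category = "angles", units = "deg",
               normalization = "none", description = "mean sagittal angle of mid-shoulder -> head center vs vertical"),
    data.frame(name = "head_angle_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the sagittal head angle"),
    data.frame(name = "trunk_tilt_mean", category = "angles", units = "deg",
               normalization = "none", description = "mean sagittal angle of mid-hip -> mid-shoulder vs vertical"),
    data.frame(name = "trunk_tilt_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the sagittal trunk tilt"),
    data.frame(name = "pelvic_obliquity_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the frontal-plane hip-to-hip angle vs x"),
    data.frame(name = "pelvic_rotation_rom", category = "angles", units = "deg",
               normalization = "none", description = "range of the transverse-plane hip-to-hip angle vs x"),
    data.frame(name = "knee_angle_at_contact", category = "angles", units = "deg",
               normalization = "none", description = "internal knee angle at the starting contact"),
    data.frame(name = "hip_angle_at_contact", category = "angles", units = "deg",
               normalization = "none", description = "internal hip angle at the starting contact")
  )
  out <- do.call(rbind, lapply(1:3, function(k) {
    b <- base
    b$step_index <- k
    b
  }))
  out <- out[!(out$name == "stride_length" & out$step_index == 1L), ]
  out$column <- sprintf("%s_s%d", out$name, out$step_index)
  rownames(out) <- NULL
  out[, c("name", "category", "step_index", "units", "normalization",
          "description", "column")]
}

#' Export the feature registry as JSON
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry_json <- function(path) {
  jsonlite::write_json(feature_registry(), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stature normalization of kinematic quantities
#'
#' Under a rigid-link scaling of the body, displacements scale with stature
#' and (pendular) velocities with its square root; accelerations are divided
#' by stature for dimensional consistency with the same scheme. Angles,
#' times and ratios are scale-free and pass through unchanged.
#'
#' @param value Numeric value(s).
#' @param kind `"displacement"`, `"velocity"`, `"acceleration"`, or `"none"`.
#' @param stature Stature in meters (> 0).
#' @return Normalized value(s).
#' @export
normalize_by_stature <- function(value,
                                 kind = c("displacement", "velocity",
                                          "acceleration", "none"),
                                 stature) {
  kind <- match.arg(kind)
  if (!is.numeric(stature) || length(stature) != 1L || !is.finite(stature) ||
      stature <= 0)
    stop("stature must be a positive number")
  switch(kind,
         displacement = value / stature,
         velocity = value / sqrt(stature),
         acceleration = value / stature,
         none = value)
}

.norm_kind <- c(by_stature = "displacement", by_sqrt_stature = "velocity",
                none = "none")

# value of one registry feature on one cycle; xs are precomputed series
.feature_value <- function(name, cyc, pre, seq) {
  side <- cyc$side
  tsel <- pre$t >= cyc$start & pre$t <= cyc$end
  swing_sel <- pre$t >= cyc$toe_off & pre$t <= cyc$end
  ankle_z <- pre$ankle_z[[side]]
  switch(name,
    walking_speed = {
      z0 <- stats::approx(pre$t, ankle_z, cyc$start)$y
      z1 <- stats::approx(pre$t, ankle_z, cyc$end)$y
      (z1 - z0) / cyc$duration
    },
    max_swing_velocity = max(pre$ankle_vz[[side]][swing_sel]),
    peak_swing_acceleration = max(pre$ankle_az[[side]][swing_sel]),
    cycle_duration = cyc$duration,
    swing_time = cyc$swing_time,
    stance_time = cyc$stance_time,
    swing_phase_ratio = cyc$swing_ratio,
    double_support_time = cyc$double_support_total,
    stride_length = {
      hz <- pre$heel_z[[side]]
      stats::approx(pre$t, hz, cyc$end)$y - stats::approx(pre$t, hz, cyc$start)$y
    },
    max_heel_height = {
      # height above the foot's own stance baseline (ground reference), so
      # the value is invariant to vertical translation of the world frame
      stance_sel <- pre$t >= cyc$start & pre$t <= cyc$toe_off
      max(pre$heel_y[[side]][swing_sel]) -
        stats::median(pre$heel_y[[side]][stance_sel])
    },
    max_toe_clearance = {
      stance_sel <- pre$t >= cyc$start & pre$t <= cyc$toe_off
      max(pre$toe_y[[side]][swing_sel]) -
        stats::median(pre$toe_y[[side]][stance_sel])
    },
    head_sway = diff(range(pre$head[tsel, "x"])),
    trunk_sway = diff(range(pre$trunk[tsel, "x"])),
    vertical_trunk_movement = diff(range(pre$trunk[tsel, "y"])),
    step_width = {
      if (is.na(cyc$opposite_contact)) return(NA_real_)
      xl <- stats::approx(pre$t, pre$ankle_x$left, cyc$opposite_contact)$y
      xr <- stats::approx(pre$t, pre$ankle_x$right, cyc$opposite_contact)$y
      abs(xl - xr)
    },
    knee_rom = diff(range(pre$knee_angle[[side]][tsel])),
    hip_rom = diff(range(pre$hip_angle[[side]][tsel])),
    ankle_rom = diff(range(pre$ankle_angle[[side]][tsel])),
    head_angle_mean = mean(pre$head_angle[tsel]),
    head_angle_rom = diff(range(pre$head_angle[tsel])),
    trunk_tilt_mean = mean(pre$trunk_tilt[tsel]),
    trunk_tilt_rom = diff(range(pre$trunk_tilt[tsel])),
    pelvic_obliquity_rom = diff(range(pre$pelvic_obliquity[tsel])),
    pelvic_rotation_rom = diff(range(pre$pelvic_rotation[tsel])),
    knee_angle_at_contact =
      stats::approx(pre$t, pre$knee_angle[[side]], cyc$start)$y,
    hip_angle_at_contact =
      stats::approx(pre$t, pre$hip_angle[[side]], cyc$start)$y,
    stop("unknown feature: ", name)
  )
}

# precompute the kinematic series the recipes consume
.precompute <- function(seq, cutoff = 6) {
  fs <- seq$frame_rate
  dt <- 1 / fs
  comp <- derive_composites(seq)
  sides <- c("left", "right")
  gx <- function(nm, ax) seq$coords[, nm, ax]
  ankle_z <- lapply(sides, function(s)
    smooth_lowpass(gx(paste0(s, "_ankle"), "z"), fs, cutoff))
  names(ankle_z) <- sides
  ankle_vz <- lapply(ankle_z, differentiate, dt = dt)
  ankle_az <- lapply(ankle_vz, differentiate, dt = dt)
  ang <- function(s) {
    hip <- seq$coords[, paste0(s, "_hip"), ]
    knee <- seq$coords[, paste0(s, "_knee"), ]
    ankle <- seq$coords[, paste0(s, "_ankle"), ]
    toe <- seq$coords[, paste0(s, "_foot_index"), ]
    list(knee = internal_joint_angle(hip, knee, ankle),
         hip = internal_joint_angle(comp$mid_shoulder, hip, knee),
         ankle = internal_joint_angle(knee, ankle, toe))
  }
  al <- ang("left"); ar <- ang("right")
  hiphip <- seq$coords[, "left_hip", ] - seq$coords[, "right_hip", ]
  list(
    t = seq$time,
    ankle_z = ankle_z, ankle_vz = ankle_vz, ankle_az = ankle_az,
    ankle_x = list(left = gx("left_ankle", "x"), right = gx("right_ankle", "x")),
    heel_z = list(left = gx("left_heel", "z"), right = gx("right_heel", "z")),
    heel_y = list(left = gx("left_heel", "y"), right = gx("right_heel", "y")),
    toe_y = list(left = gx("left_foot_index", "y"),
                 right = gx("right_foot_index", "y")),
    head = comp$head_center, trunk = comp$trunk_center,
    knee_angle = list(left = al$knee, right = ar$knee),
    hip_angle = list(left = al$hip, right = ar$hip),
    ankle_angle = list(left = al$ankle, right = ar$ankle),
    head_angle = external_angle(comp$mid_shoulder, comp$head_center,
                                reference = "y", plane = "sagittal"),
    trunk_tilt = external_angle(comp$mid_hip, comp$mid_shoulder,
                                reference = "y", plane = "sagittal"),
    pelvic_obliquity = external_angle(seq$coords[, "right_hip", ],
                                      seq$coords[, "left_hip", ],
                                      reference = "x", plane = "frontal"),
    pelvic_rotation = external_angle(seq$coords[, "right_hip", ],
                                     seq$coords[, "left_hip", ],
                                     reference = "x", plane = "transverse")
  )
}

#' Compute a trial's feature vector
#'
#' Evaluates every registry feature from its kinematic recipe on the matching
#' gait cycle and applies the stature normalization recorded in the registry.
#' Features of a step whose cycle is unavailable are NA, with the reason in
#' the `missing` attribute.
#'
#' @param seq A `pose_sequence` (with `meta` carrying stature when
#'   `normalize = TRUE`).
#' @param cycles A `gait_cycles` data frame from [build_cycles()] /
#'   [segment_trial()].
#' @param normalize Apply stature normalization (default TRUE).
#' @param registry The feature catalogue (defaults to [feature_registry()]).
#' @return Named numeric vector over `registry$column`; attributes
#'   `missing` (named character vector of reasons) and `step_sides`.
#' @export
compute_trial_features <- function(seq, cycles, normalize = TRUE,
                                   registry = feature_registry()) {
  if (normalize && is.null(seq$meta))
    stop("normalization requires trial metadata with stature")
  stature <- if (normalize) seq$meta$stature_m else NA_real_
  pre <- .precompute(seq)
  vals <- stats::setNames(rep(NA_real_, nrow(registry)), registry$column)
  missing <- character()
  for (i in seq_len(nrow(registry))) {
    k <- registry$step_index[i]
    cyc <- cycles[cycles$step_index == k, ]
    if (!nrow(cyc)) {
      missing[registry$column[i]] <- sprintf("no cycle for step %d", k)
      next
    }
    v <- tryCatch(.feature_value(registry$name[i], cyc[1, ], pre, seq),
                  error = function(e) NA_real_)
    if (is.null(v) || !length(v) || is.na(v)) {
      missing[registry$column[i]] <- "recipe failed on this cycle"
      next
    }
    if (normalize)
      v <- normalize_by_stature(v, .norm_kind[[registry$normalization[i]]],
                                stature)
    vals[registry$column[i]] <- v
  }
  sides <- stats::setNames(rep(NA_character_, 3L), paste0("s", 1:3))
  for (k in cycles$step_index) sides[paste0("s", k)] <-
    cycles$side[cycles$step_index == k][1]
  attr(vals, "missing") <- missing
  attr(vals, "step_sides") <- sides
  vals
}

#' Extract a tidy feature table from a set of trials
#'
#' Runs segmentation ([segment_trial()]) and feature computation
#' ([compute_trial_features()]) on each trial and binds one row per trial:
#' metadata columns, per-step cycle sides, then the 77 feature columns.
#' Trials whose segmentation fails yield all-NA feature rows (reason in the
#' `failures` attribute) so that downstream missing-data policy can act.
#'
#' @param trials List of `pose_sequence` objects (or [simulate_walk()]
#'   results, whose `$sequence` is used).
#' @param normalize Stature-normalize (default TRUE).
#' @param ... Passed to [segment_trial()].
#' @return Data frame; attribute `failures` maps trial index to the error.
#' @export
extract_features <- function(trials, normalize = TRUE, ...) {
  registry <- feature_registry()
  rows <- list()
  failures <- character()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    seq <- if (inherits(tr, "pose_sequence")) tr else tr$sequence
    m <- seq$meta
    meta_df <- data.frame(
      participant_id = if (is.null(m)) sprintf("trial%03d", i) else m$participant_id,
      sex = if (is.null(m)) NA_character_ else m$sex,
      stature_m = if (is.null(m)) NA_real_ else m$stature_m,
      fall_history = if (is.null(m)) NA_integer_ else m$fall_history,
      trial_index = if (is.null(m)) i else m$trial_index,
      cohort = if (is.null(m)) NA_character_ else m$cohort)
    fv <- tryCatch({
      cyc <- segment_trial(seq, ...)
      compute_trial_features(seq, cyc, normalize = normalize,
                             registry = registry)
    }, error = function(e) e)
    if (inherits(fv, "error")) {
      failures[as.character(i)] <- conditionMessage(fv)
      fv <- stats::setNames(rep(NA_real_, nrow(registry)), registry$column)
      attr(fv, "step_sides") <- stats::setNames(rep(NA_character_, 3), paste0("s", 1:3))
    }
    sides <- attr(fv, "step_sides")
    side_df <- data.frame(side_s1 = sides[["s1"]], side_s2 = sides[["s2"]],
                          side_s3 = sides[["s3"]])
    rows[[i]] <- cbind(meta_df, side_df, as.data.frame(as.list(fv)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Aggregate trial-level features to participant level
#'
#' `mean_of_trials` averages each feature over a participant's available
#' trials. In addition, two derived aggregate families are emitted as
#' supplementary columns (not part of the 77): `<name>_lr_diff`, the mean of
#' a feature over left-side cycles minus right-side cycles among steps 1-3
#' (NA when a trial lacks both sides), and `<name>_d12`, the step-1 minus
#' step-2 value.
#'
#' @param features Feature table from [extract_features()].
#' @param mode `"mean_of_trials"` (one row per participant) or `"per_trial"`
#'   (returns the table with derived columns added, one row per trial).
#' @return Data frame.
#' @export
aggregate_features <- function(features,
                               mode = c("mean_of_trials", "per_trial")) {
  mode <- match.arg(mode)
  if (!nrow(features)) stop("empty feature table")
  reg <- feature_registry()
  base_names <- unique(reg$name)
  # derived per-trial columns
  for (nm in base_names) {
    cols <- sprintf("%s_s%d", nm, 1:3)
    cols <- cols[cols %in% names(features)]
    vals <- as.matrix(features[, cols, drop = FALSE])
    sidem <- as.matrix(features[, sprintf("side_%s", sub(".*_", "", cols)), drop = FALSE])
    lr <- vapply(seq_len(nrow(features)), function(i) {
      l <- vals[i, sidem[i, ] == "left"]
      r <- vals[i, sidem[i, ] == "right"]
      if (!length(l) || !length(r)) return(NA_real_)
      mean(l, na.rm = TRUE) - mean(r, na.rm = TRUE)
    }, numeric(1))
    features[[paste0(nm, "_lr_diff")]] <- lr
    c1 <- paste0(nm, "_s1"); c2 <- paste0(nm, "_s2")
    features[[paste0(nm, "_d12")]] <-
      if (all(c(c1, c2) %in% names(features))) features[[c1]] - features[[c2]]
      else NA_real_
  }
  if (mode == "per_trial") return(features)
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "trial_index")
  split_idx <- split(seq_len(nrow(features)), features$participant_id)
  rows <- lapply(split_idx, function(ii) {
    first <- features[ii[1], c("participant_id", "sex", "stature_m",
                               "fall_history", "cohort")]
    means <- colMeans(features[ii, num_cols, drop = FALSE], na.rm = TRUE)
    means[is.nan(means)] <- NA_real_
    first$n_trials <- length(ii)
    cbind(first, as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
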