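test_that("the catalogue has 77 entries with the printed category counts", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 77L)
  for (k in 1:3) {
    cnt <- table(reg$category[reg$step_index == k])
    expect_identical(unname(cnt["speed_accel"]), 3L)
    expect_identical(unname(cnt["time"]), 5L)
    expect_identical(unname(cnt["distance_height"]), if (k == 1) 6L else 7L)
    expect_identical(unname(cnt["angles"]), 11L)
  }
  # stride length is undefined at the first step
  expect_identical(sum(reg$name == "stride_length" & reg$step_index == 1), 0L)
  expect_identical(anyDuplicated(reg$column), 0L)
})

test_that("stature normalization follows the scaling scheme", {
  expect_equal(normalize_by_stature(0.16, "displacement", 1.6), 0.10)
  expect_equal(normalize_by_stature(1.2, "velocity", 1.6), 1.2 / sqrt(1.6))
  expect_equal(normalize_by_stature(2.0, "acceleration", 1.6), 1.25)
  expect_equal(normalize_by_stature(55, "none", 1.6), 55)
  expect_error(normalize_by_stature(1, "displacement", 0), "positive")
})

test_that("programmed feature values are recovered from a clean walk", {
  sw <- fixture_walk_clean()
  fv <- fixture_features_clean()
  expect_identical(length(fv), 77L)
  expect_identical(sum(is.na(fv)), 0L)
  H <- 1.65
  for (k in 1:3) {
    expect_lt(abs(fv[sprintf("swing_phase_ratio_s%d", k)] -
                    sw$truth$swing_fraction), 0.03)
    expect_lt(abs(fv[sprintf("knee_rom_s%d", k)] - sw$truth$knee_rom) /
                sw$truth$knee_rom, 0.10)
    expect_equal(unname(fv[sprintf("max_heel_height_s%d", k)]),
                 sw$truth$max_heel_height / H, tolerance = 0.02)
    expect_equal(unname(fv[sprintf("cycle_duration_s%d", k)]),
                 sw$truth$cycle_duration, tolerance = 0.02)
  }
  # walking speed, stature-normalized, step 2
  expect_equal(unname(fv["walking_speed_s2"]),
               sw$truth$walking_speed_by_step[2] / sqrt(H), tolerance = 0.02)
  # stride at step 2: two step lengths at cruise
  expect_equal(unname(fv["stride_length_s2"]),
               (sw$truth$strike_z[4] - sw$truth$strike_z[2]) / H,
               tolerance = 0.02)
})

test_that("a programmed 50-degree knee ROM is recovered within 10%", {
  sw <- simulate_walk(gait_params(noise_sd = 0, knee_rom_amp = 50), 6,
                      meta = trial_meta("P1", "male", 1.75))
  cyc <- segment_trial(sw$sequence)
  fv <- compute_trial_features(sw$sequence, cyc)
  expect_gt(fv["knee_rom_s2"], 45)
  expect_lt(fv["knee_rom_s2"], 55)
})

test_that("missing cycles flag that step's features with a reason", {
  sw <- fixture_walk_clean()
  cyc <- fixture_cycles_clean()
  two <- cyc[cyc$step_index != 3, ]
  fv <- compute_trial_features(sw$sequence, two)
  s3 <- grepl("_s3$", names(fv))
  expect_true(all(is.na(fv[s3])))
  expect_true(all(!is.na(fv[!s3])))
  expect_match(attr(fv, "missing")[["knee_rom_s3"]], "no cycle for step 3")
})

test_that("distance features are invariant to uniform body scaling", {
  m1 <- trial_meta("A", "female", 1.60)
  m2 <- trial_meta("A", "female", 1.60 * 1.15)
  p1 <- gait_params(stature = 1.60, noise_sd = 0)
  sc <- 1.15
  p2 <- gait_params(stature = 1.60 * sc, step_length = p1$step_length * sc,
                    heel_lift_amp = p1$heel_lift_amp * sc,
                    toe_clearance_amp = p1$toe_clearance_amp * sc,
                    head_sway_amp = p1$head_sway_amp * sc,
                    trunk_sway_amp = p1$trunk_sway_amp * sc,
                    vertical_bob_amp = p1$vertical_bob_amp * sc,
                    noise_sd = 0)
  f1 <- compute_trial_features(simulate_walk(p1, 6, meta = m1)$sequence,
                               segment_trial(simulate_walk(p1, 6)$sequence))
  f2 <- compute_trial_features(simulate_walk(p2, 6, meta = m2)$sequence,
                               segment_trial(simulate_walk(p2, 6)$sequence))
  reg <- feature_registry()
  dh <- reg$column[reg$category == "distance_height"]
  expect_equal(unname(f1[dh]), unname(f2[dh]), tolerance = 0.02)
})

test_that("features are invariant to rigid translation of the trajectory", {
  sw <- fixture_walk_clean()
  fv <- fixture_features_clean()
  seq2 <- sw$sequence
  for (i in 1:3) seq2$coords[, , i] <- seq2$coords[, , i] + c(0.2, 0.05, -1)[i]
  fv2 <- compute_trial_features(seq2, segment_trial(seq2))
  expect_equal(unname(fv2), unname(fv), tolerance = 1e-6)
})

test_that("heel lift and cadence drive their features monotonically", {
  amps <- c(0.06, 0.10, 0.14)
  h <- vapply(amps, function(a) {
    sw <- simulate_walk(gait_params(noise_sd = 0, heel_lift_amp = a), 6,
                        meta = trial_meta("P1", "female", 1.65))
    fv <- compute_trial_features(sw$sequence, segment_trial(sw$sequence))
    unname(fv["max_heel_height_s2"])
  }, numeric(1))
  expect_true(all(diff(h) > 0))
  cads <- c(1.6, 1.9, 2.2)
  cd <- vapply(cads, function(cc) {
    sw <- simulate_walk(gait_params(noise_sd = 0, cadence = cc), 6,
                        meta = trial_meta("P1", "female", 1.65))
    fv <- compute_trial_features(sw$sequence, segment_trial(sw$sequence))
    unname(fv["cycle_duration_s2"])
  }, numeric(1))
  expect_true(all(diff(cd) < 0))
})

test_that("aggregation averages trials and emits derived differences", {
  sw <- fixture_walk_clean()
  ft <- extract_features(list(sw$sequence, sw$sequence))
  expect_identical(nrow(ft), 2L)
  agg <- aggregate_features(ft)
  # identical trials: the mean equals any single trial
  fcols <- feature_registry()$column
  expect_equal(unname(unlist(agg[1, fcols])), unname(unlist(ft[1, fcols])),
               tolerance = 1e-12)
  # step1 - step2 derived difference
  expect_equal(agg$swing_time_d12,
               agg$swing_time_s1 - agg$swing_time_s2, tolerance = 1e-12)
  # left-right difference uses the recorded cycle sides (L, R, L)
  expect_equal(agg$knee_rom_lr_diff,
               (agg$knee_rom_s1 + agg$knee_rom_s3) / 2 - agg$knee_rom_s2,
               tolerance = 1e-12)
  expect_error(aggregate_features(ft[0, ]), "empty")
})

test_that("mean_of_trials averages plain numbers as expected", {
  df <- data.frame(participant_id = "P1", sex = "f", stature_m = 1.6,
                   fall_history = 0L, trial_index = 1:3, cohort = "training",
                   side_s1 = "left", side_s2 = "right", side_s3 = "left",
                   swing_time_s1 = c(0.30, 0.32, 0.34))
  agg <- aggregate_features(df)
  expect_equal(agg$swing_time_s1, 0.32)
  expect_identical(agg$n_trials, 3L)
})
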