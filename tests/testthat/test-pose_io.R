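test_that("CSV round-trip is the identity on coordinates and metadata", {
  seq <- toy_sequence()
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(seq, path)
  back <- read_pose_csv(path)
  expect_equal(back$coords, seq$coords, tolerance = 1e-9)
  expect_equal(back$time, seq$time, tolerance = 1e-9)
  expect_identical(unclass(back$meta), unclass(seq$meta))
})

test_that("JSON-lines round-trip preserves the sequence", {
  seq <- toy_sequence(n = 10)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_pose_jsonl(seq, path)
  back <- read_pose_jsonl(path)
  expect_equal(back$coords, seq$coords, tolerance = 1e-9)
  expect_identical(back$meta$participant_id, "T01")
})

test_that("schema violations are reported by name", {
  seq <- toy_sequence(n = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(seq, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df$right_heel_z <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_pose_csv(path), "right_heel_z")

  df2 <- utils::read.csv(path, check.names = FALSE)
  df2$right_heel_z <- 0
  df2$time[3] <- df2$time[2]   # duplicate timestamp
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_pose_csv(path), "not strictly increasing")
})

test_that("simulator frame count matches its sampling grid", {
  p <- gait_params(noise_sd = 0, onset_time = 0.5)
  sw <- simulate_walk(p, n_steps = 5)
  dur <- 0.5 + 5 / p$cadence + 0.8
  expect_identical(n_frames(sw$sequence), as.integer(floor(dur * p$fps)) + 1L)
})

test_that("composites are means of their defining points", {
  coords <- matrix(0, 33, 3, dimnames = list(landmark_names(), c("x", "y", "z")))
  coords["left_hip", ] <- c(0.1, 1.0, 0)
  coords["right_hip", ] <- c(-0.1, 1.0, 0)
  coords["left_shoulder", ] <- c(0.2, 1.4, 0)
  coords["right_shoulder", ] <- c(-0.2, 1.4, 0)
  coords["left_hip", 3] <- 0.1; coords["right_hip", 3] <- 0.1
  comp <- derive_composites(coords)
  expect_equal(drop(comp$mid_hip), c(x = 0, y = 1.0, z = 0.1))
  # hand-computed centroid of the four trunk points
  expect_equal(drop(comp$trunk_center), c(x = 0, y = 1.2, z = 0.05))

  # degenerate: all defining points coincide
  coords[c("left_hip", "right_hip", "left_shoulder", "right_shoulder"), ] <-
    matrix(rep(c(1, 2, 3), each = 4), 4)
  expect_equal(drop(derive_composites(coords)$trunk_center), c(x = 1, y = 2, z = 3))
})

test_that("derive_composites commutes with rigid translation", {
  seq <- toy_sequence(n = 8)
  shift <- c(0.3, -0.1, 2.5)
  seq2 <- seq
  for (i in 1:3) seq2$coords[, , i] <- seq2$coords[, , i] + shift[i]
  c1 <- derive_composites(seq)
  c2 <- derive_composites(seq2)
  for (nm in names(c1))
    expect_equal(sweep(c2[[nm]], 2, shift), c1[[nm]], tolerance = 1e-12)
})

test_that("interpolate_gaps fills short interior gaps only", {
  seq <- toy_sequence(n = 12)
  # no gaps: identity
  out <- interpolate_gaps(seq)
  expect_equal(out$coords, seq$coords)
  expect_identical(nrow(attr(out, "gap_report")), 0L)

  # single missing frame: linear midpoint
  seq$coords[5, "left_knee", "y"] <- NA
  seq$coords[4, "left_knee", "y"] <- 1.0
  seq$coords[6, "left_knee", "y"] <- 1.2
  out <- interpolate_gaps(seq, max_gap = 3)
  expect_equal(out$coords[5, "left_knee", "y"], 1.1)

  # gap longer than max_gap stays missing and is reported
  seq$coords[5:9, "right_wrist", "x"] <- NA
  out <- interpolate_gaps(seq, max_gap = 3)
  expect_true(all(is.na(out$coords[5:9, "right_wrist", "x"])))
  rep <- attr(out, "gap_report")
  expect_identical(rep$reason[rep$landmark == "right_wrist"], "too_long")

  # boundary gap cannot be extrapolated
  seq$coords[1, "nose", "z"] <- NA
  out <- interpolate_gaps(seq, max_gap = 3)
  expect_true(is.na(out$coords[1, "nose", "z"]))
  rep <- attr(out, "gap_report")
  expect_identical(rep$reason[rep$landmark == "nose"], "boundary")
})

test_that("resample_uniform returns a uniform grid when jitter is large", {
  seq <- toy_sequence(n = 20)
  jit <- seq
  set.seed(4)
  jit$time <- jit$time + c(0, runif(18, -0.01, 0.01), 0)
  jit$time <- sort(jit$time)
  out <- resample_uniform(jit)
  expect_lt(max(abs(diff(out$time) - 1 / 30)), 1e-9)
  # already-uniform input is untouched
  expect_identical(resample_uniform(seq), seq)
})

test_that("pose_sequence validates its invariants", {
  tm <- trial_meta("A", "female", 1.6)
  expect_error(pose_sequence(1, array(0, c(1, 33, 3)), 30, tm), "2 frames")
  expect_error(pose_sequence(c(0, 0.1), array(0, c(2, 30, 3)), 30), "33")
  expect_error(trial_meta("A", "female", 3.0), "stature")
  expect_error(trial_meta("A", "female", 1.6, trial_index = 4), "trial_index")
})
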