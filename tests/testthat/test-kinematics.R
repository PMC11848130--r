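test_that("low-pass smoothing has unit DC gain and preserves the passband", {
  fs <- 100
  t <- seq(0, 5, by = 1 / fs)
  expect_equal(smooth_lowpass(rep(2.5, length(t)), fs, 6), rep(2.5, length(t)),
               tolerance = 1e-9)
  # 1 Hz sinusoid far below a 6 Hz cutoff: amplitude preserved within 1%
  x <- sin(2 * pi * 1 * t)
  y <- smooth_lowpass(x, fs, 6)
  mid <- t > 1 & t < 4
  expect_lt(abs(max(y[mid]) - 1), 0.01)
  # noise suppression: output closer to the clean signal than the input
  set.seed(11)
  reduction <- replicate(10, {
    xn <- x + rnorm(length(t), 0, 0.2)
    yn <- smooth_lowpass(xn, fs, 6)
    sqrt(mean((yn - x)^2)) / sqrt(mean((xn - x)^2))
  })
  expect_true(all(reduction < 1))
  expect_error(smooth_lowpass(x, fs, 60), "Nyquist")
})

test_that("differentiation is exact on constants and ramps", {
  dt <- 0.01
  expect_equal(differentiate(rep(3, 50), dt), rep(0, 50))
  x <- 0.4 * seq(0, by = dt, length.out = 100)
  expect_equal(differentiate(x, dt), rep(0.4, 100), tolerance = 1e-12)
  expect_error(differentiate(c(1, 2), dt), "3 samples")
  # y = 0.05 sin(2 pi t) at 100 Hz: peak speed 0.05 * 2 pi within 0.5%
  t <- seq(0, 3, by = dt)
  v <- differentiate(0.05 * sin(2 * pi * t), dt)
  expect_equal(max(abs(v)), 0.05 * 2 * pi, tolerance = 0.005)
})

test_that("differentiate inverts cumulative summation on a uniform grid", {
  set.seed(21)
  dt <- 0.02
  v <- rnorm(200)
  x <- cumsum(v) * dt
  back <- differentiate(x, dt)
  # central differences recover the average of adjacent increments
  expect_equal(back[2:199], (v[2:199] + v[3:200]) / 2, tolerance = 1e-10)
})

test_that("internal joint angle matches closed forms and is rigid-invariant", {
  expect_equal(internal_joint_angle(c(0, 1, 0), c(0, 0, 0), c(0, -1, 0)), 180)
  expect_equal(internal_joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(internal_joint_angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45)
  expect_error(internal_joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
  set.seed(7)
  for (i in 1:20) {
    A <- rnorm(3); B <- rnorm(3); C <- rnorm(3)
    base <- internal_joint_angle(A, B, C)
    th <- runif(3, -pi, pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rx %*% Rz
    s <- rnorm(3)
    expect_equal(internal_joint_angle(drop(R %*% A) + s, drop(R %*% B) + s,
                                      drop(R %*% C) + s),
                 base, tolerance = 1e-9)
  }
})

test_that("external angle sign convention follows the right-hand rule", {
  expect_equal(external_angle(c(0, 0, 0), c(0, 1, 0), "y", "sagittal"), 0)
  # trunk tilted 10 degrees forward of vertical
  v <- c(0, cos(10 * pi / 180), sin(10 * pi / 180))
  expect_equal(external_angle(c(0, 0, 0), v, "y", "sagittal"), 10)
  # hip-to-hip vector vs x in the frontal plane: arctan(0.1 / 1)
  expect_equal(external_angle(c(0, 0, 0), c(1, 0.1, 0), "x", "frontal"),
               atan2(0.1, 1) * 180 / pi)
  expect_error(external_angle(c(0, 0, 0), c(1, 0, 0), "x", "sagittal"),
               "does not lie")
  expect_error(external_angle(c(0, 0, 0), c(1, 0, 0), "y", "sagittal"),
               "degenerate")
})

test_that("reflection across the reference axis negates the external angle", {
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(3)
    if (v[2] == 0 && v[3] == 0) next
    a1 <- external_angle(c(0, 0, 0), v, "y", "sagittal")
    vr <- c(v[1], v[2], -v[3])  # reflect across the y axis within y-z
    a2 <- external_angle(c(0, 0, 0), vr, "y", "sagittal")
    if (abs(abs(a1) - 180) > 1e-9) expect_equal(a2, -a1, tolerance = 1e-9)
  }
})

test_that("series_stats uses the population sd and honours the interval", {
  t <- seq(0, 1, by = 0.1)
  s <- series_stats(rep(2, 11), t)
  expect_equal(c(s$min, s$max, s$range, s$mean, s$sd), c(2, 2, 0, 2, 0))
  s2 <- series_stats(c(1, 3), c(0, 1))
  expect_equal(c(s2$mean, s2$range, s2$sd), c(2, 2, 1))
  # sinusoid over whole periods: range ~ 2a
  tt <- seq(0, 2, by = 1 / 200)
  s3 <- series_stats(0.7 * sin(2 * pi * 3 * tt), tt)
  expect_equal(s3$range, 1.4, tolerance = 0.01)
  expect_error(series_stats(1:5, 1:5, c(10, 11)), "empty interval")
  # interval subsetting
  s4 <- series_stats(1:11, t, c(0, 0.35))
  expect_equal(s4$n, 4L)
  expect_equal(s4$max, 4)
})
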