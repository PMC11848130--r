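#' Zero-phase low-pass smoothing of a sampled waveform
#'
#' 4th-order Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so the output is zero-phase with unit DC gain.
#' The series is reflection-padded at both ends before filtering to suppress
#' edge transients. Human gait kinematics live below ~6 Hz, which is the
#' default cutoff.
#'
#' @param x Numeric vector sampled uniformly at `fs` Hz.
#' @param fs Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz); must be below the Nyquist rate.
#' @param order Filter order (applied twice by filtfilt).
#' @return Smoothed vector, same length as `x`.
#' @export
smooth_lowpass <- function(x, fs, cutoff = 6, order = 4) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  if (cutoff >= fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist rate ", fs / 2, " Hz")
  n <- length(x)
  if (n < 8L) return(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # demean so the filter transient acts on a zero-baseline signal (a constant
  # series passes through exactly), and reflection-pad the ends
  m <- mean(x)
  x0 <- x - m
  pad <- min(n - 1L, max(12L, ceiling(3 * fs / cutoff)))
  xp <- c(2 * x0[1] - rev(x0[2:(pad + 1L)]), x0,
          2 * x0[n] - rev(x0[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + n)] + m
}

#' Differentiate a uniformly sampled series
#'
#' Central differences in the interior, one-sided differences at the two
#' ends. Units of the result are source-units per second. Exact for linear
#' ramps everywhere.
#'
#' @param x Numeric vector (>= 3 samples).
#' @param dt Sample interval in seconds (e.g. `1/frame_rate`).
#' @return Numeric vector of the same length.
#' @export
differentiate <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("differentiate needs at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1L]) / dt
  v
}

#' Internal joint angle (3-point vertex angle)
#'
#' The angle at vertex B between rays BA and BC, in degrees within
#' \[0, 180\] - e.g. the knee angle from hip, knee, ankle. Invariant under
#' rigid rotation and translation.
#'
#' @param A,B,C 3-vectors, or `n x 3` matrices of per-frame points.
#' @return Angle(s) in degrees.
#' @export
internal_joint_angle <- function(A, B, C) {
  A <- rbind(A); B <- rbind(B); C <- rbind(C)
  u <- A - B; v <- C - B
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  if (any(nu == 0) || any(nv == 0))
    stop("internal_joint_angle: zero-length ray (A or C coincides with B)")
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  ang <- acos(cosang) * 180 / pi
  if (length(ang) == 1L) as.numeric(ang) else ang
}

# ordered in-plane basis (e1, e2) with e1 x e2 = plane normal
.plane_basis <- list(
  sagittal   = list(e1 = "y", e2 = "z", normal = "x"),  # y-z plane
  frontal    = list(e1 = "x", e2 = "y", normal = "z"),  # x-y plane
  transverse = list(e1 = "z", e2 = "x", normal = "y")   # z-x plane
)

#' External joint angle (body vector vs a global axis, in a plane)
#'
#' Signed angle between the projection of the vector P -> Q onto a body plane
#' and a global reference axis lying in that plane, in degrees in
#' (-180, 180\]. Sign follows the right-hand rule about the plane normal
#' (sagittal: +x; frontal: +z; transverse: +y).
#'
#' @param P,Q 3-vectors or `n x 3` matrices (vector is Q - P).
#' @param reference Reference axis, `"x"`, `"y"` or `"z"`; must lie in `plane`.
#' @param plane `"sagittal"` (y-z), `"frontal"` (x-y) or `"transverse"` (z-x).
#' @return Signed angle(s) in degrees.
#' @export
external_angle <- function(P, Q, reference = c("y", "x", "z"),
                           plane = c("sagittal", "frontal", "transverse")) {
  reference <- match.arg(reference)
  plane <- match.arg(plane)
  pb <- .plane_basis[[plane]]
  if (!reference %in% c(pb$e1, pb$e2))
    stop("reference axis ", reference, " does not lie in the ", plane, " plane")
  P <- rbind(P); Q <- rbind(Q)
  v <- Q - P
  colnames(v) <- .axes
  a <- v[, pb$e1]; b <- v[, pb$e2]
  if (any(a == 0 & b == 0))
    stop("external_angle: degenerate projection onto the ", plane, " plane")
  # angle from e1 toward e2 is +; reference may be either in-plane axis
  ang <- if (reference == pb$e1) atan2(b, a) else atan2(-a, b)
  ang <- ang * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  if (length(ang) == 1L) as.numeric(ang) else unname(ang)
}

#' Basic statistics of a waveform over an interval
#'
#' min, max, range, mean and population standard deviation of the samples
#' with `t0 <= t <= t1`. The population (not sample) sd is used: the frames
#' are the whole waveform, not a sample from it.
#'
#' @param values Numeric vector.
#' @param times Sample times (s), same length.
#' @param interval `c(t0, t1)`; defaults to the full span.
#' @return List with `min`, `max`, `range`, `mean`, `sd`, `n`.
#' @export
series_stats <- function(values, times, interval = range(times)) {
  stopifnot(length(values) == length(times))
  keep <- times >= interval[1] & times <= interval[2]
  if (!any(keep)) stop("series_stats: empty interval")
  v <- values[keep]
  m <- mean(v)
  list(min = min(v), max = max(v), range = max(v) - min(v), mean = m,
       sd = sqrt(mean((v - m)^2)), n = length(v))
}
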