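#' Local minima of a series with prominence and separation constraints
#'
#' A sample is a candidate minimum if it is the smallest value in its
#' immediate neighbourhood. Its prominence is how far the series must rise,
#' on its lower flank side, before descending below the candidate again (the
#' standard topographic definition, applied to the negated series). Candidates
#' closer together than `min_separation` samples are thinned, keeping the
#' deepest.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence (same units as `x`).
#' @param min_separation Minimum index distance between reported minima.
#' @return Integer vector of indices, increasing.
#' @keywords internal
find_local_minima <- function(x, min_prominence = 0, min_separation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] <= x[1:(n - 2L)] & x[2:(n - 1L)] <= x[3:n] &
                  (x[2:(n - 1L)] < x[1:(n - 2L)] | x[2:(n - 1L)] < x[3:n])) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    # climb left until a value lower than x[i] is met; track the highest point
    left <- if (i > 1L) {
      seg <- x[1:(i - 1L)]
      lower <- which(seg < x[i])
      hi <- if (length(lower)) seg[(max(lower) + 1L):(i - 1L)] else seg
      if (length(hi)) max(hi) else x[i]
    } else x[i]
    right <- if (i < n) {
      seg <- x[(i + 1L):n]
      lower <- which(seg < x[i])
      hi <- if (length(lower)) seg[1:(min(lower) - 1L)] else seg
      if (length(hi)) max(hi) else x[i]
    } else x[i]
    min(left, right) - x[i]
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer())
  # thin by separation, deepest (largest prominence) first
  o <- order(-promk)
  chosen <- integer()
  for (i in o) {
    if (!length(chosen) || all(abs(keep[i] - chosen) >= min_separation))
      chosen <- c(chosen, keep[i])
  }
  sort(chosen)
}

# sustained forward-motion interval of the record: c(start of the first,
# end of the last) run of mid-hip forward speed >= v_thresh lasting >= hold
.gait_interval <- function(seq, v_thresh = 0.1, hold = 0.2, cutoff = 6) {
  comp <- derive_composites(seq)
  dt <- 1 / seq$frame_rate
  z <- smooth_lowpass(comp$mid_hip[, "z"], seq$frame_rate, cutoff)
  vz <- differentiate(z, dt)
  ok <- vz >= v_thresh
  need <- max(1L, ceiling(hold * seq$frame_rate))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    stop("no-gait: forward mid-hip speed never meets ", v_thresh,
         " m/s for ", hold, " s")
  c(seq$time[starts[hit[1]]], seq$time[ends[hit[length(hit)]]])
}

#' Detect gait initiation from forward pelvis speed
#'
#' The walk starts from quiet standing; onset is the earliest time at which
#' the forward (z) speed of the mid-hip point meets `v_thresh` continuously
#' for at least `hold` seconds. Speed is computed from the smoothed mid-hip
#' z trajectory.
#'
#' @param seq A `pose_sequence` beginning in quiet standing.
#' @param v_thresh Speed threshold (m/s).
#' @param hold Required continuous exceedance (s).
#' @param cutoff Smoothing cutoff (Hz) for the pelvis trajectory.
#' @return Onset time (s).
#' @export
detect_onset <- function(seq, v_thresh = 0.1, hold = 0.2, cutoff = 6) {
  if (v_thresh <= 0) return(seq$time[1])  # degenerate threshold: any motion
  .gait_interval(seq, v_thresh, hold, cutoff)[1]
}

#' Detect heel strikes and toe-offs for one side
#'
#' Heel strikes are local minima of the smoothed vertical ankle velocity
#' after gait onset - the moment the heel meets the ground is the end of the
#' foot's rapid descent. Candidate minima must have prominence of at least
#' `prom_frac` of the velocity's interquartile range and be separated by at
#' least `min_separation` seconds; each candidate is then refined to the
#' extremum of a lightly smoothed velocity within `refine_window` seconds,
#' and a half-frame discretization correction is applied (the true contact
#' falls between samples, on the stance side of the extremum sample).
#' Toe-off is the maximum upward ankle velocity between consecutive
#' same-side heel strikes (and, for the first strike, in the window of one
#' swing duration before it), refined the same way.
#'
#' @param seq A `pose_sequence`.
#' @param side `"left"` or `"right"`.
#' @param onset Gait onset time; computed by [detect_onset()] when `NULL`.
#' @param cutoff Smoothing cutoff (Hz) for candidate localization.
#' @param refine_cutoff Cutoff (Hz) of the lightly smoothed velocity used for
#'   sub-window refinement.
#' @param prom_frac Prominence threshold as a fraction of the velocity IQR.
#' @param depth_frac Depth gate: minima must reach this fraction of the
#'   deepest post-onset downward velocity.
#' @param min_separation Minimum event separation (s).
#' @param refine_window Half-width (s) of the refinement window.
#' @param min_strikes Fewest heel strikes required before an
#'   insufficient-steps error is raised.
#' @return Data frame with columns `side`, `kind` (`heel_strike`/`toe_off`),
#'   `time`, `frame_index`, time-ordered.
#' @export
detect_contacts <- function(seq, side = c("left", "right"), onset = NULL,
                            cutoff = 5, refine_cutoff = 8, prom_frac = 0.10,
                            depth_frac = 0.4, min_separation = 0.3,
                            refine_window = 0.12, min_strikes = 2L) {
  side <- match.arg(side)
  gi <- tryCatch(.gait_interval(seq), error = function(e) NULL)
  if (is.null(onset)) {
    if (is.null(gi)) stop("no-gait: cannot locate gait onset")
    onset <- gi[1]
  }
  # contacts can only occur while the walker advances (plus the landing of
  # the final step); gating out quiet standing removes noise dips there
  t_end <- if (!is.null(gi)) gi[2] + min_separation else Inf
  fs <- seq$frame_rate
  dt <- 1 / fs
  y <- landmark_xyz(seq, paste0(side, "_ankle"))[, "y"]
  v_raw <- differentiate(y, dt)
  v <- smooth_lowpass(v_raw, fs, cutoff)
  v_fine <- smooth_lowpass(v_raw, fs, refine_cutoff)
  in_gait <- seq$time > onset & seq$time <= t_end
  prom <- prom_frac * stats::IQR(v[in_gait])
  sep <- max(1L, round(min_separation * fs))
  mins <- find_local_minima(v, min_prominence = prom, min_separation = sep)
  mins <- mins[in_gait[mins]]
  # a heel-strike minimum is a deep downward spike; reject shallow dips
  # (filter undershoot, residual noise) relative to the deepest descent
  if (length(mins)) {
    floor_v <- min(v[in_gait])
    mins <- mins[v[mins] <= depth_frac * floor_v]
  }
  if (length(mins) < min_strikes)
    stop("insufficient-steps: found ", length(mins), " ", side,
         " heel-strike candidate(s), need ", min_strikes)
  w <- max(2L, round(refine_window * fs))
  n <- length(v)
  # sub-frame event time: the smoothed velocity steps at the event (down-step
  # ends at a strike, up-step starts a toe-off); the half-amplitude crossing
  # of a zero-phase-smoothed step sits at the step itself.
  half_cross <- function(i, what = c("strike", "toe_off")) {
    what <- match.arg(what)
    lo <- max(1L, i - w); hi <- min(n, i + w)
    if (what == "strike") {
      m <- lo + which.min(v_fine[lo:hi]) - 1L
      th <- 0.5 * v_fine[m]
      j <- m
      while (j < min(n, m + 2L * w) && v_fine[j + 1L] < th) j <- j + 1L
      if (j == min(n, m + 2L * w)) return(seq$time[m])
      # crossing between j and j+1
      tt <- seq$time[j] + (th - v_fine[j]) / (v_fine[j + 1L] - v_fine[j]) * dt
    } else {
      m <- lo + which.max(v_fine[lo:hi]) - 1L
      th <- 0.5 * v_fine[m]
      j <- m
      while (j > max(1L, m - 2L * w) && v_fine[j - 1L] > th) j <- j - 1L
      if (j == max(1L, m - 2L * w)) return(seq$time[m])
      tt <- seq$time[j - 1L] + (th - v_fine[j - 1L]) / (v_fine[j] - v_fine[j - 1L]) * dt
    }
    tt
  }
  hs_time <- sort(unique(vapply(mins, half_cross, numeric(1), what = "strike")))
  events <- data.frame(side = side, kind = "heel_strike", time = hs_time,
                       frame_index = pmax(1L, findInterval(hs_time, seq$time)))
  # toe-offs: max upward velocity between consecutive strikes, and before the
  # first strike (the swing that leads into it)
  hs_idx <- events$frame_index
  windows <- cbind(c(max(1L, hs_idx[1] - round(0.9 * fs)),  # <= 0.9 s lookback
                     hs_idx[-length(hs_idx)]),
                   hs_idx)
  for (r in seq_len(nrow(windows))) {
    a <- windows[r, 1]; b <- windows[r, 2]
    if (b - a < 3L) next
    j <- a + which.max(v_fine[a:b]) - 1L
    if (v_fine[j] <= 0) next   # no upward swing in this window
    to_time <- half_cross(j, "toe_off")
    events <- rbind(events, data.frame(side = side, kind = "toe_off",
                                       time = to_time,
                                       frame_index = pmax(1L, findInterval(to_time, seq$time))))
  }
  events <- events[order(events$time), ]
  rownames(events) <- NULL
  events
}

#' Segment the first n steps into gait cycles
#'
#' Step k is the gait cycle starting at the k-th heel strike (either foot)
#' after onset and ending at the next same-side heel strike. Within each
#' cycle, stance runs from the starting strike to the same-side toe-off and
#' swing from that toe-off to the cycle end; total double support is the
#' summed time within the cycle during which both feet are in stance.
#' A foot whose first recorded event is a toe-off is taken to have been in
#' stance from the start of the record (standing start).
#'
#' @param contacts_left,contacts_right Event data frames from
#'   [detect_contacts()].
#' @param n_steps Number of steps to segment (default 3).
#' @param onset Optional onset time; strikes at or before it are ignored.
#' @return Data frame of class `gait_cycles`: `step_index`, `side`, `start`,
#'   `toe_off`, `end`, `opposite_contact`, `duration`, `stance_time`,
#'   `swing_time`, `swing_ratio`, `double_support_total`.
#' @export
build_cycles <- function(contacts_left, contacts_right, n_steps = 3L,
                         onset = -Inf) {
  ev <- rbind(contacts_left, contacts_right)
  ev <- ev[order(ev$time), ]
  strikes <- ev[ev$kind == "heel_strike" & ev$time > onset, ]
  # per-side stance intervals: strike -> next same-side toe-off; a side whose
  # first event is a toe-off stood on the ground from the beginning
  stance_intervals <- function(side) {
    e <- ev[ev$side == side, ]
    out <- NULL
    open_from <- if (nrow(e) && e$kind[1] == "toe_off") -Inf else NA_real_
    for (i in seq_len(nrow(e))) {
      if (e$kind[i] == "heel_strike") {
        if (is.na(open_from)) open_from <- e$time[i]
      } else if (!is.na(open_from)) {
        out <- rbind(out, c(open_from, e$time[i]))
        open_from <- NA_real_
      }
    }
    if (!is.na(open_from)) out <- rbind(out, c(open_from, Inf))
    out
  }
  st_l <- stance_intervals("left")
  st_r <- stance_intervals("right")
  overlap_in <- function(a, b, win) {
    # total overlap of interval sets a, b clipped to win
    tot <- 0
    for (i in seq_len(NROW(a))) for (j in seq_len(NROW(b))) {
      lo <- max(a[i, 1], b[j, 1], win[1])
      hi <- min(a[i, 2], b[j, 2], win[2])
      if (hi > lo) tot <- tot + (hi - lo)
    }
    tot
  }
  cycles <- NULL
  for (k in seq_len(n_steps)) {
    if (k > nrow(strikes))
      stop("insufficient-steps: no heel strike for step ", k)
    s <- strikes[k, ]
    same <- strikes[strikes$side == s$side & strikes$time > s$time, ]
    if (!nrow(same))
      stop("insufficient-steps: no closing same-side heel strike for step ", k)
    e_time <- same$time[1]
    to <- ev[ev$side == s$side & ev$kind == "toe_off" &
               ev$time > s$time & ev$time < e_time, ]
    if (!nrow(to))
      stop("insufficient-steps: no toe-off inside the cycle of step ", k)
    opp <- strikes[strikes$side != s$side & strikes$time > s$time &
                     strikes$time < e_time, ]
    ds <- overlap_in(st_l, st_r, c(s$time, e_time))
    cycles <- rbind(cycles, data.frame(
      step_index = k, side = s$side, start = s$time, toe_off = to$time[1],
      end = e_time,
      opposite_contact = if (nrow(opp)) opp$time[1] else NA_real_,
      duration = e_time - s$time,
      stance_time = to$time[1] - s$time,
      swing_time = e_time - to$time[1],
      swing_ratio = (e_time - to$time[1]) / (e_time - s$time),
      double_support_total = ds))
  }
  rownames(cycles) <- NULL
  class(cycles) <- c("gait_cycles", "data.frame")
  cycles
}

#' Run onset, contact detection and cycle segmentation for a trial
#'
#' @param seq A `pose_sequence`.
#' @param n_steps Steps to segment (default 3).
#' @param ... Passed to [detect_contacts()].
#' @return A `gait_cycles` data frame; attributes `onset` and `events`.
#' @export
segment_trial <- function(seq, n_steps = 3L, ...) {
  onset <- detect_onset(seq)
  cl <- detect_contacts(seq, "left", onset = onset, ...)
  cr <- detect_contacts(seq, "right", onset = onset, ...)
  cyc <- build_cycles(cl, cr, n_steps = n_steps, onset = onset)
  attr(cyc, "onset") <- onset
  attr(cyc, "events") <- rbind(cl, cr)[order(c(cl$time, cr$time)), ]
  cyc
}

#' Export detected events to CSV
#' @param events Event data frame (`side,kind,time,frame_index`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("side", "kind", "time", "frame_index")], path,
                   row.names = FALSE)
  invisible(path)
}
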