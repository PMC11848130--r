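#' Trial metadata
#'
#' Per-trial metadata accompanying a pose sequence: who walked, their stature,
#' their fall-history label (any fall in the past year), which of the three
#' recorded walks this is, and the cohort the trial belongs to.
#'
#' @param participant_id Character identifier.
#' @param sex `"male"` or `"female"`.
#' @param stature_m Standing height in meters, in (0.5, 2.5).
#' @param fall_history 0/1: any fall during the past year.
#' @param trial_index Trial number 1-3.
#' @param cohort `"training"` or `"validation"`.
#' @return A `trial_meta` list.
#' @export
trial_meta <- function(participant_id, sex = c("male", "female"),
                       stature_m, fall_history = 0L, trial_index = 1L,
                       cohort = c("training", "validation")) {
  sex <- match.arg(sex)
  cohort <- match.arg(cohort)
  stopifnot(is.numeric(stature_m), length(stature_m) == 1L)
  if (!is.finite(stature_m) || stature_m <= 0.5 || stature_m >= 2.5)
    stop("stature_m must lie in (0.5, 2.5) m, got ", stature_m)
  if (!fall_history %in% c(0L, 1L)) stop("fall_history must be 0 or 1")
  if (!trial_index %in% 1:3) stop("trial_index must be 1, 2 or 3")
  structure(list(
    participant_id = as.character(participant_id),
    sex = sex, stature_m = as.numeric(stature_m),
    fall_history = as.integer(fall_history),
    trial_index = as.integer(trial_index), cohort = cohort
  ), class = "trial_meta")
}

#' Construct a pose sequence
#'
#' The raw input of everything downstream: an ordered time series of the 33
#' landmarks' 3D world coordinates plus trial metadata. Coordinates use a
#' right-handed frame with y up, z forward (walking direction) and x to the
#' walker's left; units are meters.
#'
#' @param time Numeric vector of frame times (s), strictly increasing.
#' @param coords Numeric array `n_frames x 33 x 3`; landmark dimension named
#'   as [landmark_names()], axis dimension named `x`, `y`, `z`. NA marks a
#'   dropped landmark sample (see [interpolate_gaps()]).
#' @param frame_rate Nominal sampling rate in Hz.
#' @param meta A [trial_meta()] object (optional but required by the feature
#'   extractor for stature normalization).
#' @param visibility Optional `n_frames x 33` matrix of scores in \[0, 1\].
#' @return A `pose_sequence` object.
#' @export
pose_sequence <- function(time, coords, frame_rate, meta = NULL,
                          visibility = NULL) {
  nm <- landmark_names()
  if (length(dim(coords)) != 3L || dim(coords)[2] != 33L || dim(coords)[3] != 3L)
    stop("coords must be an n x 33 x 3 array")
  n <- dim(coords)[1]
  if (length(time) != n) stop("time length must match coords frames")
  if (n < 2L) stop("a pose sequence needs at least 2 frames")
  if (any(diff(time) <= 0)) stop("frame times must be strictly increasing")
  dimnames(coords) <- list(NULL, nm, .axes)
  if (!is.null(visibility)) {
    stopifnot(nrow(visibility) == n, ncol(visibility) == 33L)
    bad <- visibility[is.finite(visibility)]
    if (length(bad) && (min(bad) < 0 || max(bad) > 1))
      stop("visibility scores must lie in [0, 1]")
    colnames(visibility) <- nm
  }
  if (!is.null(meta) && !inherits(meta, "trial_meta"))
    stop("meta must be a trial_meta object")
  structure(list(time = as.numeric(time), coords = coords,
                 frame_rate = as.numeric(frame_rate), meta = meta,
                 visibility = visibility),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames @ %.6g Hz, %.2f s span\n",
              length(x$time), x$frame_rate, diff(range(x$time))))
  if (!is.null(x$meta))
    cat(sprintf("  participant %s (%s, %.2f m), fall_history=%d, trial %d, %s\n",
                x$meta$participant_id, x$meta$sex, x$meta$stature_m,
                x$meta$fall_history, x$meta$trial_index, x$meta$cohort))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$time)

# landmark trajectory as an n x 3 matrix
#' Extract one landmark's trajectory
#' @param seq A `pose_sequence`.
#' @param name A landmark name from [landmark_names()].
#' @return `n_frames x 3` matrix with columns x, y, z.
#' @export
landmark_xyz <- function(seq, name) {
  if (!name %in% landmark_names()) stop("unknown landmark: ", name)
  seq$coords[, name, , drop = TRUE]
}

.sidecar_path <- function(path) sub("\\.[^.]+$", "", path) |> paste0(".meta.json")

#' Write a pose sequence to CSV (+ JSON sidecar)
#'
#' Columns `frame,time,<name>_x,<name>_y,<name>_z[,<name>_v]` for the 33
#' topology names, UTF-8, `.` decimal. Metadata is written to a sidecar JSON
#' (`<stem>.meta.json`) next to the CSV.
#'
#' @param seq A `pose_sequence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(seq, path) {
  nm <- landmark_names()
  df <- data.frame(frame = seq_along(seq$time) - 1L, time = seq$time)
  for (ln in nm) for (ax in .axes)
    df[[paste0(ln, "_", ax)]] <- seq$coords[, ln, ax]
  if (!is.null(seq$visibility))
    for (ln in nm) df[[paste0(ln, "_v")]] <- seq$visibility[, ln]
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(frame_rate = seq$frame_rate)
  if (!is.null(seq$meta)) side <- c(side, unclass(seq$meta))
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pose sequence from CSV
#'
#' Inverse of [write_pose_csv()]. Frames are sorted by time; all 33 landmark
#' coordinate columns must be present. Metadata is read from the JSON sidecar
#' when it exists.
#'
#' @param path CSV path.
#' @param frame_rate Sampling rate; defaults to the sidecar value or, failing
#'   that, the median inter-frame interval.
#' @return A `pose_sequence`.
#' @export
read_pose_csv <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("frame", "time") %in% names(df)))
    stop("pose CSV must contain 'frame' and 'time' columns")
  nm <- landmark_names()
  need <- as.vector(outer(nm, .axes, function(a, b) paste0(a, "_", b)))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("pose CSV schema error: missing landmark column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[order(df$time), , drop = FALSE]
  if (any(diff(df$time) <= 0))
    stop("pose CSV data error: frame times are not strictly increasing")
  n <- nrow(df)
  coords <- array(NA_real_, c(n, 33L, 3L), dimnames = list(NULL, nm, .axes))
  for (ln in nm) for (ax in .axes)
    coords[, ln, ax] <- df[[paste0(ln, "_", ax)]]
  vis <- NULL
  vcols <- paste0(nm, "_v")
  if (all(vcols %in% names(df))) {
    vis <- as.matrix(df[, vcols])
    colnames(vis) <- nm
  }
  meta <- NULL
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (is.null(frame_rate) && !is.null(side$frame_rate))
      frame_rate <- side$frame_rate
    if (!is.null(side$participant_id))
      meta <- trial_meta(side$participant_id, side$sex, side$stature_m,
                         side$fall_history, side$trial_index, side$cohort)
  }
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(df$time))
  pose_sequence(df$time, coords, frame_rate, meta = meta, visibility = vis)
}

#' Write / read a pose sequence as JSON lines
#'
#' One frame object per line with keys `frame`, `time` and per-landmark
#' `[x, y, z]` triplets; a leading header line holds `frame_rate` and the
#' trial metadata.
#'
#' @param seq A `pose_sequence`.
#' @param path Output path.
#' @return `path` (write) or a `pose_sequence` (read).
#' @export
write_pose_jsonl <- function(seq, path) {
  nm <- landmark_names()
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- list(frame_rate = seq$frame_rate)
  if (!is.null(seq$meta)) hdr <- c(hdr, unclass(seq$meta))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_along(seq$time)) {
    lms <- lapply(nm, function(ln) unname(seq$coords[i, ln, ]))
    names(lms) <- nm
    rec <- c(list(frame = i - 1L, time = seq$time[i]), lms)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_pose_jsonl
#' @export
read_pose_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) stop("JSON-lines pose file too short")
  hdr <- jsonlite::fromJSON(lines[1])
  nm <- landmark_names()
  n <- length(lines) - 1L
  time <- numeric(n)
  coords <- array(NA_real_, c(n, 33L, 3L), dimnames = list(NULL, nm, .axes))
  for (i in seq_len(n)) {
    rec <- jsonlite::fromJSON(lines[i + 1L])
    time[i] <- rec$time
    for (ln in nm) coords[i, ln, ] <- rec[[ln]]
  }
  meta <- NULL
  if (!is.null(hdr$participant_id))
    meta <- trial_meta(hdr$participant_id, hdr$sex, hdr$stature_m,
                       hdr$fall_history, hdr$trial_index, hdr$cohort)
  o <- order(time)
  pose_sequence(time[o], coords[o, , , drop = FALSE], hdr$frame_rate, meta = meta)
}

#' Composite joints derived from the 33-point topology
#'
#' Joints not present in the raw topology, computed per frame as midpoints or
#' centroids of measured points: `mid_hip` (hips), `mid_shoulder` (shoulders),
#' `trunk_center` (both shoulders + both hips), and `head_center` (nose +
#' both ears).
#'
#' @param seq A `pose_sequence`, or a single frame given as a named
#'   `33 x 3` matrix (rownames from [landmark_names()]).
#' @return List of `n x 3` matrices (`1 x 3` for a single frame):
#'   `mid_hip`, `mid_shoulder`, `trunk_center`, `head_center`.
#' @export
derive_composites <- function(seq) {
  get <- function(nm) {
    if (inherits(seq, "pose_sequence")) {
      m <- seq$coords[, nm, , drop = FALSE]
      # average across the landmark dimension
      apply(m, c(1, 3), mean)
    } else {
      matrix(colMeans(seq[nm, , drop = FALSE]), 1, 3,
             dimnames = list(NULL, .axes))
    }
  }
  list(
    mid_hip      = get(c("left_hip", "right_hip")),
    mid_shoulder = get(c("left_shoulder", "right_shoulder")),
    trunk_center = get(c("left_shoulder", "right_shoulder",
                         "left_hip", "right_hip")),
    head_center  = get(c("nose", "left_ear", "right_ear"))
  )
}

#' Fill short dropped-landmark gaps by linear interpolation
#'
#' Gaps are runs of NA coordinates for one landmark axis. Interior gaps of
#' length `<= max_gap` frames are filled by per-axis linear interpolation;
#' longer gaps and gaps touching the sequence boundary are left untouched and
#' listed in the report.
#'
#' @param seq A `pose_sequence`.
#' @param max_gap Longest gap (frames) that will be filled.
#' @return The sequence with gaps filled; attribute `"gap_report"` is a data
#'   frame (`landmark`, `axis`, `start_frame`, `length`, `filled`, `reason`).
#' @export
interpolate_gaps <- function(seq, max_gap = 3L) {
  coords <- seq$coords
  rep_rows <- list()
  n <- dim(coords)[1]
  for (ln in landmark_names()) for (ax in .axes) {
    v <- coords[, ln, ax]
    na <- is.na(v)
    if (!any(na)) next
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]; len <- e - s + 1L
      boundary <- s == 1L || e == n
      fill <- !boundary && len <= max_gap
      if (fill) {
        v[s:e] <- stats::approx(seq$time[c(s - 1L, e + 1L)],
                                v[c(s - 1L, e + 1L)],
                                xout = seq$time[s:e])$y
      }
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        landmark = ln, axis = ax, start_frame = s, length = len,
        filled = fill,
        reason = if (fill) "" else if (boundary) "boundary" else "too_long")
    }
    coords[, ln, ax] <- v
  }
  out <- seq
  out$coords <- coords
  attr(out, "gap_report") <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(landmark = character(), axis = character(),
               start_frame = integer(), length = integer(),
               filled = logical(), reason = character())
  out
}

#' Resample a pose sequence to a uniform time grid
#'
#' Finite differencing downstream assumes uniform sampling. When inter-frame
#' jitter exceeds `tol` (relative to the nominal frame period) the sequence is
#' linearly resampled onto a uniform `1/frame_rate` grid spanning the original
#' record; otherwise it is returned unchanged.
#'
#' @param seq A `pose_sequence`.
#' @param tol Relative jitter tolerance (default 1%).
#' @return A `pose_sequence` on a uniform grid.
#' @export
resample_uniform <- function(seq, tol = 0.01) {
  dt <- 1 / seq$frame_rate
  jit <- max(abs(diff(seq$time) - dt)) / dt
  if (jit <= tol) return(seq)
  grid <- seq(seq$time[1], seq$time[length(seq$time)], by = dt)
  nm <- landmark_names()
  coords <- array(NA_real_, c(length(grid), 33L, 3L),
                  dimnames = list(NULL, nm, .axes))
  for (ln in nm) for (ax in .axes)
    coords[, ln, ax] <- stats::approx(seq$time, seq$coords[, ln, ax],
                                      xout = grid)$y
  pose_sequence(grid, coords, seq$frame_rate, meta = seq$meta)
}
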