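# Session/time data model and CSV IO for joint-angle and insole recordings.
#
# Angle CSV dialect:  time_s, <channel>...      (degrees; booleans as 0/1)
# Insole CSV dialect: time_s, <sensor_id>...    (N/cm^2)
# Layout CSV:         sensor_id, length_pct, width_pct
#   length_pct: 0 = posterior heel, 100 = toe tip
#   width_pct:  0 = medial edge,    100 = lateral edge

#' Describe a measurement session
#'
#' A session identifies one capture of one worker at one measurement time
#' (`pre` = start of shift, `post` = after three hours of uninterrupted work).
#'
#' @param worker_id Character or numeric worker identifier.
#' @param phase `"pre"` or `"post"`.
#' @param duration_s Session length in seconds (> 0).
#' @param sample_rate_hz Sampling rate in frames per second (> 0).
#' @return An object of class `ergo_session`.
#' @export
session <- function(worker_id, phase = c("pre", "post"), duration_s, sample_rate_hz) {
  phase <- match.arg(phase)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || !is.finite(duration_s) || duration_s <= 0)
    stop_ergo("duration_s must be a single positive number, got %s", format(duration_s))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L || sample_rate_hz <= 0)
    stop_ergo("sample_rate_hz must be a single positive number")
  structure(list(worker_id = as.character(worker_id), phase = phase,
                 duration_s = duration_s, sample_rate_hz = sample_rate_hz),
            class = "ergo_session")
}

#' Required joint-angle channels
#'
#' The channel set the RULA and CUELA scorers consume. Angle channels are in
#' degrees, flexion positive / extension negative; `*_left`/`*_right` suffixes
#' mark the body side. Channels listed by [boolean_angle_channels()] are
#' 0/1 modifier traces (IMU exports do not encode worksheet checkbox items
#' directly, so they are accepted as traces).
#'
#' @return Character vector of channel names.
#' @export
required_angle_channels <- function() {
  c("upper_arm_flexion_left", "upper_arm_flexion_right",
    "upper_arm_abduction_left", "upper_arm_abduction_right",
    "shoulder_raised_left", "shoulder_raised_right",
    "lower_arm_flexion_left", "lower_arm_flexion_right",
    "wrist_flexion_left", "wrist_flexion_right",
    "wrist_deviation_left", "wrist_deviation_right",
    "wrist_twist_left", "wrist_twist_right",
    "neck_flexion", "neck_twist", "neck_side_bend",
    "trunk_flexion", "trunk_twist", "trunk_side_bend",
    "legs_supported")
}

#' @rdname required_angle_channels
#' @export
boolean_angle_channels <- function() {
  c("shoulder_raised_left", "shoulder_raised_right",
    "neck_twist", "neck_side_bend", "trunk_twist", "trunk_side_bend",
    "legs_supported")
}

#' Construct a joint-angle series
#'
#' @param time_s Numeric vector of frame times in seconds, starting at 0,
#'   strictly increasing, regularly sampled.
#' @param angles Numeric matrix or data.frame, one column per channel.
#' @param session An [session()] object; if `NULL` one is built from the time
#'   vector.
#' @param channels Required channel names (defaults to
#'   [required_angle_channels()]).
#' @return Object of class `joint_angle_series` with elements `session`,
#'   `time_s`, `angles` (numeric matrix), `channels`.
#' @export
joint_angle_series <- function(time_s, angles, session = NULL,
                               channels = required_angle_channels()) {
  angles <- as.matrix(angles)
  storage.mode(angles) <- "double"
  n <- length(time_s)
  if (n == 0L) stop_ergo("joint-angle series must contain at least one frame")
  if (nrow(angles) != n)
    stop_ergo("angle traces have %d frames but time vector has %d", nrow(angles), n)
  missing <- setdiff(channels, colnames(angles))
  if (length(missing))
    stop_ergo("missing required channel(s): %s", paste(missing, collapse = ", "))
  bad <- which(!is.finite(angles), arr.ind = TRUE)
  if (nrow(bad))
    stop_ergo("non-finite angle values at frame(s) %s",
              paste(utils::head(unique(bad[, 1L]), 10L), collapse = ", "))
  ang_chan <- setdiff(channels, boolean_angle_channels())
  if (any(abs(angles[, ang_chan, drop = FALSE]) > 180))
    stop_ergo("angle values outside [-180, 180] degrees")
  bool_chan <- intersect(boolean_angle_channels(), colnames(angles))
  bv <- angles[, bool_chan, drop = FALSE]
  if (!all(bv %in% c(0, 1)))
    stop_ergo("boolean modifier channels must contain only 0/1 values")
  if (is.null(session)) {
    rate <- infer_sample_rate(time_s)
    session <- session("unknown", "pre", duration_s = n / rate, sample_rate_hz = rate)
  }
  structure(list(session = session, time_s = as.numeric(time_s),
                 angles = angles, channels = colnames(angles)),
            class = "joint_angle_series")
}

# Median inter-frame gap; regular sampling enforced to 1% tolerance.
infer_sample_rate <- function(time_s, tol = 0.01) {
  if (length(time_s) < 2L) return(NA_real_)
  d <- diff(time_s)
  if (any(d <= 0)) stop_ergo("time column must be strictly increasing")
  med <- stats::median(d)
  if (any(abs(d - med) / med > tol))
    stop_ergo("irregular sampling: inter-frame gaps deviate more than %.0f%% from the median step %.6g s",
              tol * 100, med)
  1 / med
}

#' Read a joint-angle CSV export
#'
#' Expects a header row; the first column is time in seconds (monotonically
#' increasing, regular sampling), remaining columns are named angle channels
#' in degrees. The sample rate is inferred from the median time step.
#'
#' @param path Path to the angle CSV.
#' @param channels Channels that must be present.
#' @param worker_id,phase Session metadata attached to the result.
#' @return A [joint_angle_series()].
#' @export
read_angles <- function(path, channels = required_angle_channels(),
                        worker_id = "unknown", phase = "pre") {
  df <- read_csv_checked(path)
  if (ncol(df) < 2L) stop_ergo("%s: expected a time column plus angle channels", path)
  time_s <- df[[1L]]
  if (!is.numeric(time_s)) stop_ergo("%s: first column must be numeric time in seconds", path)
  rate <- infer_sample_rate(time_s)
  if (length(time_s) == 1L) rate <- 1
  m <- as.matrix(df[, -1L, drop = FALSE])
  sess <- session(worker_id, phase, duration_s = nrow(m) / rate, sample_rate_hz = rate)
  joint_angle_series(time_s - time_s[1L], m, session = sess, channels = channels)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop_ergo("file not found: %s", path)
  df <- tryCatch(data.table::fread(path, data.table = FALSE),
                 error = function(e) stop_ergo("malformed CSV %s: %s", path, conditionMessage(e)))
  if (!nrow(df)) stop_ergo("%s: no data rows", path)
  df
}

#' Construct an insole pressure recording
#'
#' @param time_s Frame times in seconds.
#' @param pressures Frame x sensor matrix of pressures (N/cm^2), column names
#'   are sensor ids matching `layout$sensor_id`.
#' @param layout Data frame `sensor_id, length_pct, width_pct` in normalized
#'   foot coordinates (length 0 = posterior heel; width 0 = medial edge).
#' @param side `"left"` or `"right"`.
#' @param session Optional [session()].
#' @param excluded Integer indices of sensors excluded from all metrics.
#' @param max_pressure Device full-scale output; raw values above it are
#'   rejected.
#' @return Object of class `insole_recording`.
#' @export
insole_recording <- function(time_s, pressures, layout, side = c("left", "right"),
                             session = NULL, excluded = integer(),
                             max_pressure = 64) {
  side <- match.arg(side)
  pressures <- as.matrix(pressures)
  storage.mode(pressures) <- "double"
  n <- length(time_s)
  if (n == 0L || nrow(pressures) != n)
    stop_ergo("pressure matrix must have one row per time frame")
  layout <- as.data.frame(layout)
  need <- c("sensor_id", "length_pct", "width_pct")
  if (!all(need %in% names(layout)))
    stop_ergo("layout must have columns %s", paste(need, collapse = ", "))
  if (nrow(layout) > 240L)
    stop_ergo("layout has %d sensors; the device supports at most 240", nrow(layout))
  if (any(layout$length_pct < 0 | layout$length_pct > 100 |
          layout$width_pct < 0 | layout$width_pct > 100))
    stop_ergo("layout percentages must lie in [0, 100]")
  if (!setequal(colnames(pressures), layout$sensor_id) ||
      ncol(pressures) != nrow(layout))
    stop_ergo("pressure columns do not match layout sensor ids (%d columns vs %d layout sensors)",
              ncol(pressures), nrow(layout))
  pressures <- pressures[, as.character(layout$sensor_id), drop = FALSE]
  if (any(!is.finite(pressures))) stop_ergo("non-finite pressure values")
  if (any(pressures < 0)) stop_ergo("negative raw pressure values")
  if (any(pressures > max_pressure))
    stop_ergo("pressure values above the device range (%g N/cm^2)", max_pressure)
  excluded <- sort(unique(as.integer(excluded)))
  if (length(excluded) && (min(excluded) < 1L || max(excluded) > ncol(pressures)))
    stop_ergo("excluded sensor indices out of range")
  if (is.null(session)) {
    rate <- if (n > 1L) infer_sample_rate(time_s) else 1
    session <- session("unknown", "pre", duration_s = n / rate, sample_rate_hz = rate)
  }
  structure(list(session = session, side = side, time_s = as.numeric(time_s),
                 pressures = pressures, layout = layout, excluded = excluded),
            class = "insole_recording")
}

#' Read an insole pressure CSV plus its sensor layout
#'
#' @inheritParams read_angles
#' @param layout_path Path to the layout CSV
#'   (`sensor_id, length_pct, width_pct`).
#' @param side Foot side of the recording.
#' @return An [insole_recording()] with no calibration applied.
#' @export
read_insole <- function(path, layout_path, side = c("left", "right"),
                        worker_id = "unknown", phase = "pre") {
  side <- match.arg(side)
  df <- read_csv_checked(path)
  layout <- read_csv_checked(layout_path)
  time_s <- df[[1L]]
  rate <- if (length(time_s) > 1L) infer_sample_rate(time_s) else 1
  m <- as.matrix(df[, -1L, drop = FALSE])
  sess <- session(worker_id, phase, duration_s = nrow(m) / rate, sample_rate_hz = rate)
  insole_recording(time_s - time_s[1L], m, layout, side = side, session = sess)
}

#' Write angle / insole objects back to their CSV dialects
#'
#' Writing then re-reading reproduces the original object; files written by
#' these functions round-trip byte-identically through the readers.
#'
#' @param x A `joint_angle_series` or `insole_recording`.
#' @param path Output CSV path.
#' @param layout_path For recordings, optional path for the layout CSV.
#' @return `path`, invisibly.
#' @export
write_angles <- function(x, path) {
  stopifnot(inherits(x, "joint_angle_series"))
  df <- data.frame(time_s = x$time_s, x$angles, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_angles
#' @export
write_insole <- function(x, path, layout_path = NULL) {
  stopifnot(inherits(x, "insole_recording"))
  df <- data.frame(time_s = x$time_s, x$pressures, check.names = FALSE)
  data.table::fwrite(df, path)
  if (!is.null(layout_path)) data.table::fwrite(x$layout, layout_path)
  invisible(path)
}

#' Extract a half-open time window
#'
#' Frames with `start_s <= t < end_s` (times relative to recording start) are
#' retained, so adjacent windows partition the frame sequence with no
#' duplication. Session metadata is updated; times are rebased to start at 0.
#'
#' @param x A `joint_angle_series` or `insole_recording`.
#' @param start_s,end_s Window bounds in seconds, `0 <= start_s < end_s`.
#' @param ... Unused.
#' @return Object of the same class as `x`.
#' @name window-ergofield
NULL

window_frames <- function(time_s, start_s, end_s, duration_s) {
  if (!is.numeric(start_s) || !is.numeric(end_s) || start_s < 0 || start_s >= end_s)
    stop_ergo("require 0 <= start_s < end_s")
  if (start_s >= duration_s + 1e-9)
    stop_ergo("window start %.3f s is beyond the recording (%.3f s)", start_s, duration_s)
  rel <- time_s - time_s[1L]
  keep <- which(rel >= start_s & rel < end_s)
  if (!length(keep)) stop_ergo("window [%.3f, %.3f) contains no frames", start_s, end_s)
  keep
}

#' @rdname window-ergofield
#' @exportS3Method stats::window
window.joint_angle_series <- function(x, start_s = 0, end_s = x$session$duration_s, ...) {
  keep <- window_frames(x$time_s, start_s, end_s, x$session$duration_s)
  sess <- x$session
  sess$duration_s <- min(end_s, sess$duration_s) - start_s
  joint_angle_series(x$time_s[keep] - x$time_s[keep[1L]],
                     x$angles[keep, , drop = FALSE],
                     session = sess, channels = x$channels)
}

#' @rdname window-ergofield
#' @exportS3Method stats::window
window.insole_recording <- function(x, start_s = 0, end_s = x$session$duration_s, ...) {
  keep <- window_frames(x$time_s, start_s, end_s, x$session$duration_s)
  sess <- x$session
  sess$duration_s <- min(end_s, sess$duration_s) - start_s
  insole_recording(x$time_s[keep] - x$time_s[keep[1L]],
                   x$pressures[keep, , drop = FALSE], x$layout,
                   side = x$side, session = sess, excluded = x$excluded)
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> worker %s, %s: %d frames @ %.4g Hz, %d channels\n",
              x$session$worker_id, x$session$phase, length(x$time_s),
              x$session$sample_rate_hz, ncol(x$angles)))
  invisible(x)
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole_recording> worker %s, %s, %s foot: %d frames @ %.4g Hz, %d sensors (%d excluded)\n",
              x$session$worker_id, x$session$phase, x$side, length(x$time_s),
              x$session$sample_rate_hz, ncol(x$pressures), length(x$excluded)))
  invisible(x)
}

n_frames <- function(x) length(x$time_s)
frame_dt <- function(x) 1 / x$session$sample_rate_hz
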