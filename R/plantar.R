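# In-shoe plantar pressure kinetics: zero calibration, size-dependent
# rear-lateral sensor exclusion, six-region segmentation of the insole, and
# the per-region metrics (mean pressure, peak pressure, pressure-time
# impulse, loaded-time fraction, loaded-sensor percentage) plus pre/post
# contrasts.
#
# Coordinate convention: length_pct runs 0 (posterior heel) to 100 (toe tip);
# width_pct runs 0 (medial edge) to 100 (lateral edge), for both feet. Region
# bounds are contiguous half-open real intervals, upper-closed, so no sensor
# can fall into a dead band between printed integer bounds.

REGION_NAMES <- c("rearfoot", "midfoot", "metatarsal_heads", "forefoot",
                  "inner_foot", "outer_foot")

#' Zero-calibrate a recording against an unloaded baseline
#'
#' Subtracts each sensor's baseline mean (captured sitting, feet raised, so
#' that lace-binding pressure is removed) and clamps negatives to zero.
#'
#' @param recording,baseline [insole_recording()]s sharing the same layout.
#' @return The calibrated recording.
#' @export
zero_calibrate <- function(recording, baseline) {
  stopifnot(inherits(recording, "insole_recording"),
            inherits(baseline, "insole_recording"))
  if (!identical(recording$layout$sensor_id, baseline$layout$sensor_id))
    stop_ergo("recording and baseline layouts do not match")
  offs <- colMeans(baseline$pressures)
  recording$pressures <- pmax(sweep(recording$pressures, 2L, offs, "-"), 0)
  recording
}

# EU size -> number of posterior-lateral sensors excluded
REAR_LATERAL_EXCLUSION <- c("39" = 3L, "41" = 4L, "43" = 4L, "45" = 5L)

#' Exclude rear-lateral sensors affected by the safety-shoe heel guidance
#'
#' Marks the `k` most posterior-lateral sensors as excluded, where `k`
#' depends on the shoe size (EU 39: 3; EU 41/43: 4; EU 45: 5). Sensors are
#' ranked by `length_pct` ascending (most posterior first), ties broken by
#' `width_pct` descending (most lateral first). Excluded sensors never
#' contribute to any downstream metric.
#'
#' @param recording An [insole_recording()].
#' @param shoe_size EU shoe size; one of 39, 41, 43, 45.
#' @return The recording with its `excluded` set updated.
#' @export
exclude_rear_lateral <- function(recording, shoe_size) {
  stopifnot(inherits(recording, "insole_recording"))
  key <- as.character(shoe_size)
  if (!key %in% names(REAR_LATERAL_EXCLUSION))
    stop_ergo("unsupported shoe size %s (supported: EU %s)", key,
              paste(names(REAR_LATERAL_EXCLUSION), collapse = "/"))
  k <- REAR_LATERAL_EXCLUSION[[key]]
  ord <- order(recording$layout$length_pct, -recording$layout$width_pct)
  recording$excluded <- sort(unique(c(recording$excluded, ord[seq_len(k)])))
  recording
}

#' Assign sensors to the six foot regions
#'
#' Longitudinal regions partition the non-excluded sensors by foot-length
#' percentage: rearfoot `[0, 30]`, midfoot `(30, 60]`, metatarsal heads
#' `(60, 80]`, forefoot `(80, 100]`. Width regions partition them
#' independently: inner foot `[0, 60]`, outer foot `(60, 100]` of foot width
#' from the medial edge.
#'
#' @param x An [insole_recording()] or a layout data frame.
#' @param excluded Sensor indices to leave out (taken from the recording when
#'   `x` is one).
#' @return Named list of class `region_masks`: integer sensor indices per
#'   region, with the bounds attached as an attribute.
#' @export
assign_regions <- function(x, excluded = NULL) {
  if (inherits(x, "insole_recording")) {
    layout <- x$layout
    if (is.null(excluded)) excluded <- x$excluded
  } else {
    layout <- as.data.frame(x)
    if (is.null(excluded)) excluded <- integer()
  }
  keep <- setdiff(seq_len(nrow(layout)), excluded)
  l <- layout$length_pct
  w <- layout$width_pct
  bounds <- list(rearfoot = c(0, 30), midfoot = c(30, 60),
                 metatarsal_heads = c(60, 80), forefoot = c(80, 100),
                 inner_foot = c(0, 60), outer_foot = c(60, 100))
  in_band <- function(v, b, closed_low) if (closed_low) v >= b[1] & v <= b[2] else v > b[1] & v <= b[2]
  masks <- list(
    rearfoot = keep[in_band(l[keep], bounds$rearfoot, TRUE)],
    midfoot = keep[in_band(l[keep], bounds$midfoot, FALSE)],
    metatarsal_heads = keep[in_band(l[keep], bounds$metatarsal_heads, FALSE)],
    forefoot = keep[in_band(l[keep], bounds$forefoot, FALSE)],
    inner_foot = keep[in_band(w[keep], bounds$inner_foot, TRUE)],
    outer_foot = keep[in_band(w[keep], bounds$outer_foot, FALSE)])
  structure(masks, bounds = bounds, class = "region_masks")
}

#' Pressure-time impulse of a single sensor
#'
#' The impulse is the product of pressure and time accumulated over the
#' recording: `sum(p_i * dt)` in Ns/cm^2. It is additive over adjacent time
#' windows and linear in both pressure and `dt`.
#'
#' @param trace Numeric pressure trace (N/cm^2).
#' @param dt Frame duration in seconds (> 0).
#' @return Impulse in Ns/cm^2.
#' @export
sensor_impulse <- function(trace, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop_ergo("dt must be a positive number")
  sum(trace) * dt
}

#' Per-region kinetic metrics
#'
#' For each region the per-sensor statistics are averaged over the member
#' sensors:
#' * `mean_pressure` - each sensor's time-mean over its loaded frames
#'   (frames at or above `load_thresh`); sensors never loaded contribute 0.
#'   Set `mean_over = "all"` to average over the whole recording instead.
#' * `peak_pressure` - each sensor's maximum over the recording.
#' * `impulse` - each sensor's [sensor_impulse()].
#' * `loaded_time_fraction` - fraction of frames at or above `load_thresh`.
#' * `loaded_sensor_pct` - percentage of member sensors loaded in at least
#'   `persistence` of frames (default 1%), the "percentage of loaded
#'   sensors" summary.
#'
#' @param recording A calibrated [insole_recording()].
#' @param masks [assign_regions()] output; computed from the recording when
#'   `NULL`.
#' @param load_thresh Pressure counting as "loaded", default 0.6 N/cm^2 (the
#'   device's lower measurement bound).
#' @param mean_over `"loaded"` (default) or `"all"` frames for
#'   `mean_pressure`.
#' @param persistence Minimum loaded-frame fraction for a sensor to count as
#'   loaded in `loaded_sensor_pct`.
#' @return Data frame of class `region_metrics`: one row per region with
#'   columns `region, n_sensors, mean_pressure, peak_pressure, impulse,
#'   loaded_time_fraction, loaded_sensor_pct`.
#' @export
region_metrics <- function(recording, masks = NULL, load_thresh = 0.6,
                           mean_over = c("loaded", "all"), persistence = 0.01) {
  stopifnot(inherits(recording, "insole_recording"))
  mean_over <- match.arg(mean_over)
  if (is.null(masks)) masks <- assign_regions(recording)
  p <- recording$pressures
  dt <- frame_dt(recording)
  nf <- nrow(p)

  loaded <- p >= load_thresh
  n_loaded <- colSums(loaded)
  sens_mean <- if (mean_over == "loaded") {
    s <- colSums(p * loaded)
    ifelse(n_loaded > 0, s / pmax(n_loaded, 1L), 0)
  } else colMeans(p)
  sens_peak <- apply(p, 2L, max)
  sens_impulse <- colSums(p) * dt
  sens_ltf <- n_loaded / nf
  sens_is_loaded <- sens_ltf >= persistence

  rows <- lapply(names(masks), function(rn) {
    idx <- masks[[rn]]
    if (!length(idx)) stop_ergo("region '%s' has no member sensors", rn)
    data.frame(region = rn, n_sensors = length(idx),
               mean_pressure = mean(sens_mean[idx]),
               peak_pressure = mean(sens_peak[idx]),
               impulse = mean(sens_impulse[idx]),
               loaded_time_fraction = mean(sens_ltf[idx]),
               loaded_sensor_pct = 100 * mean(sens_is_loaded[idx]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("region_metrics", "data.frame")
  out
}

#' Post-minus-pre contrast of region metrics
#'
#' Signed per-region differences, positive when the post value exceeds the
#' pre value.
#'
#' @param pre,post `region_metrics` data frames (or any data frames with a
#'   `region` column and numeric metric columns) over the same region set.
#' @return Data frame with the same metric columns holding `post - pre`.
#' @export
region_contrast <- function(pre, post) {
  pre <- as.data.frame(pre); post <- as.data.frame(post)
  if (!("region" %in% names(pre)) || !("region" %in% names(post)))
    stop_ergo("both inputs need a 'region' column")
  if (!setequal(pre$region, post$region) || anyDuplicated(pre$region))
    stop_ergo("pre and post cover different region sets")
  post <- post[match(pre$region, post$region), , drop = FALSE]
  num <- intersect(names(pre)[vapply(pre, is.numeric, TRUE)],
                   names(post)[vapply(post, is.numeric, TRUE)])
  num <- setdiff(num, "n_sensors")
  out <- data.frame(region = pre$region)
  for (cn in num) out[[cn]] <- post[[cn]] - pre[[cn]]
  out
}
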