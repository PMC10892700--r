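# RULA scoring: per-frame partial scores from joint angles, worksheet lookup
# tables A/B/C, muscle-use and force modifiers, action-level time
# distributions and the continuous whole-process final score.
#
# The worksheet lookup tables (upper arm x lower arm x wrist x wrist twist ->
# A; neck x trunk x legs -> B; A x B -> grand) are shipped as an editable
# plain-text file in inst/extdata/rula_tables.csv and validated on load.
# Angle-to-partial-score bins follow the published worksheet; boundary values
# are assigned to the lower (safer) score.

#' RULA lookup tables
#'
#' Loads the worksheet lookup tables from the packaged plain-text file (or a
#' user-supplied file in the same long format `tbl,i1,i2,i3,i4,score`).
#'
#' @param path Optional path to an alternative table file.
#' @return List with arrays `A` (6 x 3 x 4 x 2), `B` (6 x 6 x 2), `C` (8 x 7).
#' @export
rula_tables <- function(path = NULL) {
  key <- if (is.null(path)) "rula_default" else paste0("rula_", path)
  if (!is.null(.ergo_cache[[key]])) return(.ergo_cache[[key]])
  file <- if (is.null(path))
    system.file("extdata", "rula_tables.csv", package = "ergofield", mustWork = TRUE)
  else path
  df <- utils::read.csv(file)
  build <- function(tbl, dims) {
    sub <- df[df$tbl == tbl, , drop = FALSE]
    arr <- array(NA_integer_, dim = dims)
    idx <- as.matrix(sub[, paste0("i", seq_along(dims)), drop = FALSE])
    arr[idx] <- sub$score
    if (any(is.na(arr))) stop_ergo("RULA table %s is incomplete in %s", tbl, file)
    arr
  }
  tabs <- list(A = build("A", c(6L, 3L, 4L, 2L)),
               B = build("B", c(6L, 6L, 2L)),
               C = build("C", c(8L, 7L)))
  if (any(tabs$C < 1L) || any(tabs$C > 7L))
    stop_ergo("RULA table C grand scores must lie in [1, 7]")
  .ergo_cache[[key]] <- tabs
  tabs
}

#' Force/load specification for the RULA modifiers
#'
#' @param load_band One of `"<2kg"`, `"2-10kg"`, `">10kg"`.
#' @param repetitive,static Whether the load is applied repeatedly (>= 4
#'   times/min) or held statically.
#' @return Object of class `force_spec`.
#' @export
force_spec <- function(load_band = c("<2kg", "2-10kg", ">10kg"),
                       repetitive = FALSE, static = FALSE) {
  load_band <- match.arg(load_band)
  structure(list(load_band = load_band, repetitive = isTRUE(repetitive),
                 static = isTRUE(static)), class = "force_spec")
}

# Worksheet force/load score: <2 kg intermittent 0; 2-10 kg +1
# (+2 static/repeated); >10 kg +2 (+3 static/repeated).
force_modifier <- function(force) {
  stopifnot(inherits(force, "force_spec"))
  held <- force$static || force$repetitive
  switch(force$load_band,
         "<2kg" = 0L,
         "2-10kg" = if (held) 2L else 1L,
         ">10kg" = if (held) 3L else 2L)
}

# ---- angle-bin partial scores (vectorized over frames) ----------------------

# Upper arm: 1 within +/-20 deg; 2 for extension beyond 20 or flexion 20-45;
# 3 for 45-90; 4 beyond 90. +1 shoulder raised, +1 abducted (> 45 deg).
score_upper_arm <- function(flex, abd, raised) {
  s <- ifelse(flex >= -20 & flex <= 20, 1L,
       ifelse(flex < -20 | flex <= 45, 2L,
       ifelse(flex <= 90, 3L, 4L)))
  pmin(s + (raised > 0) + (abd > 45), 6L)
}

# Lower arm: 1 for flexion 60-100 deg, 2 otherwise; optional midline/out-to-
# side 0/1 channel adds 1 when present in the series.
score_lower_arm <- function(flex, midline = 0) {
  s <- ifelse(flex >= 60 & flex <= 100, 1L, 2L)
  pmin(s + (midline > 0), 3L)
}

# Wrist: 1 near neutral (|flex| <= 5), 2 within +/-15, 3 beyond;
# +1 for ulnar/radial deviation beyond 10 deg.
score_wrist <- function(flex, dev) {
  s <- ifelse(abs(flex) <= 5, 1L, ifelse(abs(flex) <= 15, 2L, 3L))
  pmin(s + (abs(dev) > 10), 4L)
}

# Wrist twist: 1 in mid-range, 2 near end of range (|twist| > 45 deg).
score_wrist_twist <- function(twist) ifelse(abs(twist) > 45, 2L, 1L)

# Neck: 1 for 0-10 deg flexion, 2 for 10-20, 3 beyond 20, 4 in extension
# (below -5; a 5 deg neutral band absorbs sensor noise).
# +1 twisted, +1 side-bent.
score_neck <- function(flex, twist, side) {
  s <- ifelse(flex < -5, 4L,
       ifelse(flex <= 10, 1L, ifelse(flex <= 20, 2L, 3L)))
  pmin(s + (twist > 0) + (side > 0), 6L)
}

# Trunk: 1 within +/-5 deg (upright/supported), 2 to 20 deg, 3 to 60, 4
# beyond; extension binned by magnitude. +1 twisted, +1 side-bent.
score_trunk <- function(flex, twist, side) {
  a <- abs(flex)
  s <- ifelse(a <= 5, 1L, ifelse(a <= 20, 2L, ifelse(a <= 60, 3L, 4L)))
  pmin(s + (twist > 0) + (side > 0), 6L)
}

# Legs: 1 if legs and feet supported/balanced, 2 otherwise.
score_legs <- function(supported) ifelse(supported > 0, 1L, 2L)

# ---- table lookups ----------------------------------------------------------

# score_A/score_B include muscle-use and force modifiers; grand from table C
# with rows/columns clamped at 8/7 as on the worksheet.
lookup_grand <- function(ua, la, wr, wt, nk, tr, lg, muscle_a, force_a,
                         muscle_b, force_b, tabs = rula_tables()) {
  posture_a <- tabs$A[cbind(pmin(ua, 6L), pmin(la, 3L), pmin(wr, 4L), pmin(wt, 2L))]
  posture_b <- tabs$B[cbind(pmin(nk, 6L), pmin(tr, 6L), pmin(lg, 2L))]
  score_a <- posture_a + muscle_a + force_a
  score_b <- posture_b + muscle_b + force_b
  grand <- tabs$C[cbind(pmin(score_a, 8L), pmin(score_b, 7L))]
  list(posture_a = posture_a, posture_b = posture_b,
       score_a = score_a, score_b = score_b, grand = grand)
}

side_channels <- function(side) {
  paste0(c("upper_arm_flexion", "upper_arm_abduction", "shoulder_raised",
           "lower_arm_flexion", "wrist_flexion", "wrist_deviation",
           "wrist_twist"), "_", side)
}

# Vectorized scoring of one body side over a frame x channel matrix.
score_side_matrix <- function(m, side, force, muscle_a, muscle_b,
                              tabs = rula_tables()) {
  ch <- function(nm) m[, nm]
  sided <- function(nm) m[, paste0(nm, "_", side)]
  mid_nm <- paste0("lower_arm_midline_", side)
  midline <- if (mid_nm %in% colnames(m)) m[, mid_nm] else 0
  ua <- score_upper_arm(sided("upper_arm_flexion"), sided("upper_arm_abduction"),
                        sided("shoulder_raised"))
  la <- score_lower_arm(sided("lower_arm_flexion"), midline)
  wr <- score_wrist(sided("wrist_flexion"), sided("wrist_deviation"))
  wt <- score_wrist_twist(sided("wrist_twist"))
  nk <- score_neck(ch("neck_flexion"), ch("neck_twist"), ch("neck_side_bend"))
  tr <- score_trunk(ch("trunk_flexion"), ch("trunk_twist"), ch("trunk_side_bend"))
  lg <- score_legs(ch("legs_supported"))
  fm <- force_modifier(force)
  res <- lookup_grand(ua, la, wr, wt, nk, tr, lg,
                      as.integer(muscle_a), fm, as.integer(muscle_b), fm, tabs)
  c(list(upper_arm = ua, lower_arm = la, wrist = wr, wrist_twist = wt,
         neck = nk, trunk = tr, legs = lg,
         muscle_a = as.integer(muscle_a) + integer(length(ua)),
         force_a = fm, muscle_b = as.integer(muscle_b) + integer(length(ua)),
         force_b = fm), res)
}

#' Score a single posture frame
#'
#' Applies the worksheet partial-score bins and table lookups to one frame of
#' joint angles. Left and right limbs are scored separately; the returned
#' grand score is that of the worse (higher-scoring) side unless a side is
#' requested.
#'
#' @param angles Named numeric vector (or single-row matrix) holding all
#'   channels of [required_angle_channels()] for one frame.
#' @param force A [force_spec()].
#' @param static_a,static_b Muscle-use flags for score groups A (arms/wrists)
#'   and B (neck/trunk/legs): posture held static > 1 min or repeated >= 4
#'   times/min.
#' @param side `"worst"`, `"left"` or `"right"`.
#' @param tabs Lookup tables from [rula_tables()].
#' @return Object of class `rula_frame_score`: partial scores, `score_a`,
#'   `score_b`, modifiers, `grand` and the side that produced it.
#' @export
rula_score_frame <- function(angles, force = force_spec(),
                             static_a = FALSE, static_b = FALSE,
                             side = c("worst", "left", "right"),
                             tabs = rula_tables()) {
  side <- match.arg(side)
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1L,
                                             dimnames = list(NULL, names(angles)))
  missing <- setdiff(required_angle_channels(), colnames(angles))
  if (length(missing))
    stop_ergo("missing channel(s): %s", paste(missing, collapse = ", "))
  if (any(abs(angles) > 180)) stop_ergo("angle values outside [-180, 180]")
  sides <- if (side == "worst") c("left", "right") else side
  scored <- lapply(sides, function(s)
    score_side_matrix(angles, s, force, static_a, static_b, tabs))
  names(scored) <- sides
  pick <- if (length(scored) == 1L) 1L else which.max(vapply(scored, function(z) z$grand[1L], 0))
  out <- lapply(scored[[pick]], function(v) unname(v[1L]))
  out$side <- sides[pick]
  structure(out, class = "rula_frame_score")
}

#' @export
print.rula_frame_score <- function(x, ...) {
  cat(sprintf("<rula_frame_score> grand %d (side %s; A=%d, B=%d)\n",
              x$grand, x$side, x$score_a, x$score_b))
  invisible(x)
}

# ---- static-posture detection ----------------------------------------------

# Trailing-window running max via the block prefix/suffix-cummax trick, O(n).
roll_max_trailing <- function(x, w) {
  n <- length(x)
  if (w > n) return(rep(NA_real_, n))
  pad <- (-n) %% w
  xp <- c(x, rep(-Inf, pad))
  m <- matrix(xp, nrow = w)
  pre <- as.vector(apply(m, 2L, cummax))
  suf <- as.vector(apply(m[w:1, , drop = FALSE], 2L, cummax)[w:1, , drop = FALSE])
  out <- rep(NA_real_, n)
  i <- w:n
  out[i] <- pmax(suf[i - w + 1L], pre[i])
  out
}

#' Detect statically held postures
#'
#' A frame is flagged static when the trailing window (default 60 s, the
#' "held > 1 minute" worksheet rule) of the angle trace spans less than
#' `range_thresh_deg`. Frames earlier than one full window are non-static by
#' definition.
#'
#' @param x Numeric angle trace in degrees.
#' @param sample_rate_hz Sampling rate of the trace.
#' @param window_s Trailing window length in seconds.
#' @param range_thresh_deg Angular range below which the posture counts as
#'   held.
#' @return Logical vector, one flag per frame.
#' @export
detect_static <- function(x, sample_rate_hz, window_s = 60, range_thresh_deg = 10) {
  w <- as.integer(round(window_s * sample_rate_hz))
  n <- length(x)
  out <- rep(FALSE, n)
  if (w < 1L || w > n) return(out)
  rng <- roll_max_trailing(x, w) + roll_max_trailing(-x, w)
  out[!is.na(rng) & rng < range_thresh_deg] <- TRUE
  out
}

# ---- series scoring ---------------------------------------------------------

#' Score a whole joint-angle series
#'
#' Scores every frame for both body sides and combines them as the worse
#' (higher) per-frame grand score. Muscle-use modifiers are derived per frame
#' from [detect_static()] on the contributing channels (arms/wrists for group
#' A of each side; neck/trunk for group B) or forced on via the repetition
#' flags.
#'
#' @param series A [joint_angle_series()].
#' @param force A [force_spec()] applied to both score groups.
#' @param repetitive_a,repetitive_b Set `TRUE` when the work is known to be
#'   repetitive (>= 4 cycles/min); automatic repetition detection is out of
#'   scope.
#' @param window_s,range_thresh_deg Passed to [detect_static()].
#' @param tabs Lookup tables.
#' @return Data frame of class `rula_series_scores` with columns `time_s`,
#'   `grand_left`, `grand_right`, `grand` (worse side per frame).
#' @export
rula_score_series <- function(series, force = force_spec(),
                              repetitive_a = FALSE, repetitive_b = FALSE,
                              window_s = 60, range_thresh_deg = 10,
                              tabs = rula_tables()) {
  stopifnot(inherits(series, "joint_angle_series"))
  m <- series$angles
  rate <- series$session$sample_rate_hz
  stat <- function(nm) detect_static(m[, nm], rate, window_s, range_thresh_deg)
  static_b <- stat("neck_flexion") | stat("trunk_flexion")
  grands <- lapply(c("left", "right"), function(s) {
    static_a <- stat(paste0("upper_arm_flexion_", s)) |
      stat(paste0("lower_arm_flexion_", s)) |
      stat(paste0("wrist_flexion_", s))
    score_side_matrix(m, s, force,
                      muscle_a = static_a | repetitive_a,
                      muscle_b = static_b | repetitive_b, tabs)$grand
  })
  out <- data.frame(time_s = series$time_s,
                    grand_left = grands[[1L]], grand_right = grands[[2L]],
                    grand = pmax(grands[[1L]], grands[[2L]]))
  class(out) <- c("rula_series_scores", "data.frame")
  out
}

# ---- distributions and final score ------------------------------------------

rula_action_levels <- function() {
  c(acceptable = "acceptable",
    near_future = "measures should be initiated in the near future",
    shortly = "measures should be initiated shortly",
    directly = "measures should be initiated directly")
}

#' Risk-level time distribution
#'
#' Fraction of working time spent in each ordered risk level.
#'
#' @param levels Ordered level labels.
#' @param proportions Non-negative fractions summing to one.
#' @return Object of class `risk_distribution`.
#' @export
risk_distribution <- function(levels, proportions) {
  proportions <- as.numeric(proportions)
  if (length(levels) != length(proportions))
    stop_ergo("levels and proportions differ in length")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop_ergo("proportions must be non-negative and sum to 1")
  structure(list(levels = as.character(levels), proportions = proportions),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat("<risk_distribution>\n")
  for (i in seq_along(x$levels))
    cat(sprintf("  %-12s %6.2f%%\n", x$levels[i], 100 * x$proportions[i]))
  invisible(x)
}

#' Working-time distribution over the four RULA action levels
#'
#' Grand scores 1-2 map to action level 1 (acceptable), 3-4 to level 2
#' (measures in the near future), 5-6 to level 3 (measures shortly) and 7 to
#' level 4 (measures directly).
#'
#' @param grand Integer vector of per-frame grand scores (or a
#'   `rula_series_scores` data frame).
#' @return A [risk_distribution()] over the four action levels.
#' @export
action_level_distribution <- function(grand) {
  if (inherits(grand, "rula_series_scores")) grand <- grand$grand
  if (!length(grand)) stop_ergo("empty grand-score trace")
  if (any(grand < 1 | grand > 7)) stop_ergo("grand scores must lie in [1, 7]")
  level <- findInterval(grand, c(1, 3, 5, 7))
  p <- tabulate(level, nbins = 4L) / length(level)
  risk_distribution(names(rula_action_levels()), p)
}

#' Final whole-process RULA score
#'
#' Collapses the per-frame grand-score trace into one number representing the
#' dynamics of the whole working process. The default is the time-weighted
#' mean of the per-frame grand scores (continuous, in `[1, 7]`); the modal
#' level and the 90th percentile are available as alternatives.
#'
#' @param grand Per-frame grand scores (or a `rula_series_scores`).
#' @param method `"mean"` (default), `"mode"` or `"p90"`.
#' @return A single number in `[1, 7]`.
#' @export
final_rula_score <- function(grand, method = c("mean", "mode", "p90")) {
  method <- match.arg(method)
  if (inherits(grand, "rula_series_scores")) grand <- grand$grand
  if (!length(grand)) stop_ergo("empty grand-score trace")
  switch(method,
         mean = mean(grand),
         mode = as.numeric(names(which.max(table(grand)))),
         p90 = as.numeric(stats::quantile(grand, 0.9, type = 1)))
}
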