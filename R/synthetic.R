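# Seeded synthetic work-shift generator: sensor layouts, cyclic heel-to-toe
# gait pressure, task-dependent joint-angle streams, unloaded baseline
# captures, and Borg CR-10 / fatigue VAS surveys with programmable pre/post
# shifts and a right-dominant side asymmetry.
#
# The generator's job is to carry the statistical structure the analysis
# assumes (paired phases, side asymmetry, null pressure time effect), not to
# be a validated biomechanical gait model. Everything is reproducible from
# the spec seed via an integer-state RNG stream consumed in a fixed order.

#' Specification of a synthetic worker cohort
#'
#' Defaults mirror the emulated study design: 24 workers measured in two 12
#' min sessions (pre shift and after three hours of work), of whom the
#' production workers (3/4 of the cohort) additionally wear pressure insoles;
#' perceived-exertion shift of Cohen's d = 0.78 on a 0-10 scale; fatigue
#' shift d = 0.65; a right-dominant mean-pressure asymmetry of ratio 1.15;
#' and no pre/post change in plantar pressure.
#'
#' @param n_workers Number of workers (>= 2).
#' @param fraction_production Fraction of workers at production workstations
#'   (the rest are office workers); only production workers carry insoles.
#' @param seed Integer master seed (< 2^31).
#' @param pre_exertion_mean,exertion_sd Pre-shift Borg CR-10 exertion mean /
#'   SD.
#' @param post_shift_d Cohen's d of the pre-to-post exertion shift.
#' @param pre_fatigue_mean,fatigue_sd,fatigue_shift_d Same for the fatigue
#'   VAS.
#' @param phase_correlation Within-subject correlation of the two phases of
#'   a survey score.
#' @param side_asymmetry_ratio Right/left mean-pressure ratio (> 0).
#' @param pressure_time_effect Relative pre-to-post change in pressure
#'   amplitude (0 = none, the study condition).
#' @param session_s Session length in seconds (study: 720 s).
#' @param angle_rate_hz,pressure_rate_hz Sampling rates (study: 60 / 100 Hz).
#' @param base_peak_scale Baseline gait pressure amplitude (N/cm^2).
#' @param worker_scale_sd,session_scale_sd,side_noise_sd Log-normal SDs of
#'   the between-worker, between-session and side-specific amplitude noise.
#' @param cadence_spm Steps per minute per foot during work.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_workers = 24L, fraction_production = 0.75, seed = 1L,
                        pre_exertion_mean = 3.49, exertion_sd = 2.0,
                        post_shift_d = 0.78,
                        pre_fatigue_mean = 2.58, fatigue_sd = 2.0,
                        fatigue_shift_d = 0.65,
                        phase_correlation = 0.6,
                        side_asymmetry_ratio = 1.15,
                        pressure_time_effect = 0,
                        session_s = 720, angle_rate_hz = 60,
                        pressure_rate_hz = 100,
                        base_peak_scale = 30,
                        worker_scale_sd = 0.15, session_scale_sd = 0.05,
                        side_noise_sd = 0.05,
                        cadence_spm = 50) {
  spec <- list(n_workers = as.integer(n_workers),
               fraction_production = fraction_production, seed = as.integer(seed),
               pre_exertion_mean = pre_exertion_mean, exertion_sd = exertion_sd,
               post_shift_d = post_shift_d,
               pre_fatigue_mean = pre_fatigue_mean, fatigue_sd = fatigue_sd,
               fatigue_shift_d = fatigue_shift_d,
               phase_correlation = phase_correlation,
               side_asymmetry_ratio = side_asymmetry_ratio,
               pressure_time_effect = pressure_time_effect,
               session_s = session_s, angle_rate_hz = angle_rate_hz,
               pressure_rate_hz = pressure_rate_hz,
               base_peak_scale = base_peak_scale,
               worker_scale_sd = worker_scale_sd,
               session_scale_sd = session_scale_sd,
               side_noise_sd = side_noise_sd,
               cadence_spm = cadence_spm)
  if (spec$n_workers < 2L) stop_ergo("n_workers must be >= 2")
  if (spec$fraction_production < 0 || spec$fraction_production > 1)
    stop_ergo("fraction_production must lie in [0, 1]")
  if (spec$side_asymmetry_ratio <= 0) stop_ergo("side_asymmetry_ratio must be > 0")
  if (spec$session_s <= 0 || spec$angle_rate_hz <= 0 || spec$pressure_rate_hz <= 0)
    stop_ergo("durations and sampling rates must be positive")
  for (nm in c("post_shift_d", "fatigue_shift_d", "pressure_time_effect"))
    if (!is.finite(spec[[nm]])) stop_ergo("%s must be finite", nm)
  if (spec$phase_correlation < 0 || spec$phase_correlation >= 1)
    stop_ergo("phase_correlation must lie in [0, 1)")
  structure(spec, class = "cohort_spec")
}

#' Generate a foot-shaped sensor layout
#'
#' A grid of surface-resistive sensors in normalized foot coordinates, masked
#' to a foot-like outline. Larger shoe sizes carry more sensors (up to the
#' device maximum of 240).
#'
#' @param shoe_size EU size, one of 39, 41, 43, 45.
#' @return Layout data frame `sensor_id, length_pct, width_pct`.
#' @export
simulate_layout <- function(shoe_size = 43) {
  dims <- switch(as.character(shoe_size),
                 "39" = c(16L, 11L), "41" = c(17L, 12L),
                 "43" = c(19L, 12L), "45" = c(20L, 12L),
                 stop_ergo("unsupported shoe size %s", shoe_size))
  l <- (seq_len(dims[1L]) - 0.5) / dims[1L] * 100
  w <- (seq_len(dims[2L]) - 0.5) / dims[2L] * 100
  g <- expand.grid(length_pct = l, width_pct = w)
  # half-width fraction of the insole occupied by the foot outline
  prof <- stats::approx(x = c(0, 15, 30, 45, 60, 75, 90, 100),
                        y = c(0.80, 0.85, 0.75, 0.65, 0.90, 1.00, 0.92, 0.72),
                        xout = g$length_pct, rule = 2)$y
  keep <- abs(g$width_pct - 50) <= 50 * prof
  g <- g[keep, , drop = FALSE]
  data.frame(sensor_id = sprintf("s%03d", seq_len(nrow(g))),
             length_pct = g$length_pct, width_pct = g$width_pct,
             stringsAsFactors = FALSE)
}

#' Simulate cyclic heel-to-toe gait pressure
#'
#' Each step, a Gaussian pressure blob translates from the heel towards the
#' toes over the stance phase; the amplitude envelope dips over the midfoot
#' (arch) so rearfoot loading dominates, and the swing phase is unloaded.
#' Pressures scale linearly with `peak_scale` (until the 64 N/cm^2 device
#' ceiling) and per-step amplitude noise is multiplicative, so doubling
#' `peak_scale` under the same seed doubles every impulse.
#'
#' @param layout Sensor layout from [simulate_layout()].
#' @param duration_s,sample_rate_hz Recording length and rate.
#' @param cadence_spm Steps per minute for this foot (> 0).
#' @param peak_scale Amplitude scale in N/cm^2 (0 gives an all-zero
#'   recording).
#' @param side Foot side label.
#' @param stance_fraction Fraction of the step cycle in ground contact.
#' @param step_var_sd Log-SD of the per-step amplitude multiplier.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param session Optional [session()] metadata.
#' @return An [insole_recording()].
#' @export
simulate_gait_pressure <- function(layout, duration_s, sample_rate_hz = 100,
                                   cadence_spm = 50, peak_scale = 30,
                                   side = c("left", "right"),
                                   stance_fraction = 0.6, step_var_sd = 0.1,
                                   seed = NULL, session = NULL) {
  side <- match.arg(side)
  if (cadence_spm <= 0) stop_ergo("cadence must be positive")
  gen <- function() {
    n <- as.integer(round(duration_s * sample_rate_hz))
    t <- (seq_len(n) - 1L) / sample_rate_hz
    period <- 60 / cadence_spm
    step_idx <- floor(t / period)
    u <- (t - step_idx * period) / period
    stance <- u < stance_fraction
    s <- ifelse(stance, u / stance_fraction, NA_real_)
    step_mult <- exp(stats::rnorm(max(step_idx) + 1L, 0, step_var_sd))

    centre <- 8 + 80 * s                       # blob centre, % foot length
    # double-hump stance envelope (heel strike, push-off) combined with a
    # foot-length load profile that unloads the arch: rearfoot loading
    # dominates, the metatarsal heads carry the push-off, the midfoot least
    env <- 1.15 * exp(-(s - 0.22)^2 / (2 * 0.13^2)) +
           0.95 * exp(-(s - 0.78)^2 / (2 * 0.13^2))
    gprof <- stats::approx(x = c(0, 15, 30, 45, 60, 70, 80, 90, 100),
                           y = c(1.0, 1.1, 0.7, 0.25, 0.75, 0.95, 0.8, 0.5, 0.4),
                           xout = pmin(pmax(centre, 0), 100), rule = 2)$y
    amp <- ifelse(stance, env * gprof * step_mult[step_idx + 1L], 0)
    centre[is.na(centre)] <- 0

    sig_l <- 10; sig_w <- 24; w_c <- 52
    gl <- exp(-outer(centre, layout$length_pct, "-")^2 / (2 * sig_l^2))
    gw <- exp(-(layout$width_pct - w_c)^2 / (2 * sig_w^2))
    p <- (amp * gl) * rep(gw, each = n) * peak_scale
    p <- pmin(p, 64)
    colnames(p) <- layout$sensor_id
    insole_recording(t, p, layout, side = side, session = session)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Unloaded baseline capture: per-sensor lace-binding offsets plus read noise.
simulate_baseline <- function(layout, duration_s = 5, sample_rate_hz = 100,
                              side = "left", session = NULL,
                              offset_max = 0.8, noise_sd = 0.02) {
  n <- as.integer(round(duration_s * sample_rate_hz))
  offs <- stats::runif(nrow(layout), 0, offset_max)
  p <- matrix(pmax(rep(offs, each = n) +
                     stats::rnorm(n * nrow(layout), 0, noise_sd), 0),
              nrow = n, dimnames = list(NULL, layout$sensor_id))
  rec <- insole_recording((seq_len(n) - 1L) / sample_rate_hz, p, layout,
                          side = side, session = session)
  attr(rec, "offsets") <- offs
  rec
}

# Task-dependent posture profiles: per channel mean, sinusoid amplitude,
# work-cycle period (s) and frame noise SD; booleans carry an `on` probability
# applied blockwise (10 s blocks).
angle_task_profiles <- function() {
  chan <- function(mean, amp, period, noise) list(mean = mean, amp = amp,
                                                  period = period, noise = noise)
  list(
    production = list(
      upper_arm_flexion_left = chan(32, 30, 5, 3),
      upper_arm_flexion_right = chan(40, 32, 5, 3),
      upper_arm_abduction_left = chan(12, 14, 7, 2),
      upper_arm_abduction_right = chan(16, 16, 7, 2),
      lower_arm_flexion_left = chan(80, 28, 5, 3),
      lower_arm_flexion_right = chan(82, 30, 5, 3),
      wrist_flexion_left = chan(5, 14, 3, 2),
      wrist_flexion_right = chan(6, 16, 3, 2),
      wrist_deviation_left = chan(0, 8, 3, 1),
      wrist_deviation_right = chan(0, 9, 3, 1),
      wrist_twist_left = chan(0, 30, 4, 3),
      wrist_twist_right = chan(0, 32, 4, 3),
      neck_flexion = chan(18, 10, 9, 2),
      trunk_flexion = chan(14, 16, 11, 2),
      booleans = c(shoulder_raised_left = 0.05, shoulder_raised_right = 0.08,
                   neck_twist = 0.12, neck_side_bend = 0.05,
                   trunk_twist = 0.12, trunk_side_bend = 0.05,
                   legs_supported = 1.0)),
    office = list(
      upper_arm_flexion_left = chan(14, 5, 18, 1.5),
      upper_arm_flexion_right = chan(16, 6, 18, 1.5),
      upper_arm_abduction_left = chan(8, 4, 20, 1),
      upper_arm_abduction_right = chan(10, 4, 20, 1),
      lower_arm_flexion_left = chan(90, 6, 18, 1.5),
      lower_arm_flexion_right = chan(92, 6, 18, 1.5),
      wrist_flexion_left = chan(8, 6, 6, 1),
      wrist_flexion_right = chan(10, 7, 6, 1),
      wrist_deviation_left = chan(3, 4, 6, 0.5),
      wrist_deviation_right = chan(4, 5, 6, 0.5),
      wrist_twist_left = chan(0, 12, 8, 1.5),
      wrist_twist_right = chan(0, 14, 8, 1.5),
      neck_flexion = chan(24, 6, 15, 1.5),
      trunk_flexion = chan(6, 4, 20, 1),
      booleans = c(shoulder_raised_left = 0.02, shoulder_raised_right = 0.02,
                   neck_twist = 0.05, neck_side_bend = 0.02,
                   trunk_twist = 0.03, trunk_side_bend = 0.02,
                   legs_supported = 1.0)))
}

#' Simulate a task-dependent joint-angle stream
#'
#' Posture means plus sinusoidal work cycles plus Gaussian frame jitter per
#' channel; boolean modifier channels switch on blockwise with
#' profile-specific probabilities.
#'
#' @param profile `"production"`, `"office"`, or a profile list in the format
#'   of `angle_task_profiles()`.
#' @param duration_s,sample_rate_hz Stream length and rate.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param session Optional [session()] metadata.
#' @return A [joint_angle_series()].
#' @export
simulate_angles <- function(profile = "production", duration_s = 720,
                            sample_rate_hz = 60, seed = NULL, session = NULL) {
  if (is.character(profile)) {
    profs <- angle_task_profiles()
    if (!profile %in% names(profs)) stop_ergo("unknown task profile '%s'", profile)
    profile <- profs[[profile]]
  }
  gen <- function() {
    n <- as.integer(round(duration_s * sample_rate_hz))
    t <- (seq_len(n) - 1L) / sample_rate_hz
    chans <- setdiff(required_angle_channels(), boolean_angle_channels())
    m <- matrix(0, n, length(required_angle_channels()),
                dimnames = list(NULL, required_angle_channels()))
    for (ch in chans) {
      p <- profile[[ch]]
      if (is.null(p)) stop_ergo("profile lacks channel %s", ch)
      phase <- stats::runif(1, 0, 2 * pi)
      m[, ch] <- p$mean + p$amp * sin(2 * pi * t / p$period + phase) +
        stats::rnorm(n, 0, p$noise)
    }
    block <- pmax(1L, as.integer(round(10 * sample_rate_hz)))
    n_blocks <- ceiling(n / block)
    for (ch in boolean_angle_channels()) {
      pr <- profile$booleans[[ch]]
      states <- stats::rbinom(n_blocks, 1L, pr)
      m[, ch] <- rep(states, each = block)[seq_len(n)]
    }
    m[, chans] <- pmax(pmin(m[, chans], 180), -180)
    joint_angle_series(t, m, session = session)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# truncated-normal draw on the 0-10 survey scale
trunc_scale <- function(x) pmin(pmax(x, 0), 10)

#' Simulate a complete synthetic work-shift cohort
#'
#' For every worker and phase the generator produces a joint-angle stream;
#' production workers additionally get left/right insole recordings (with a
#' right-dominant amplitude asymmetry and, by default, no pre/post change)
#' and per-session unloaded baseline captures. Borg CR-10 body-map ratings
#' and fatigue VAS values are drawn with the programmed pre-to-post shifts
#' and within-subject phase correlation, truncated to the 0-10 scale.
#'
#' All randomness derives from `spec$seed`, so the same spec reproduces the
#' same bundle (and byte-identical files when `out_dir` is given).
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; when given, every recording is written
#'   as CSV (via [write_angles()] / [write_insole()]) together with
#'   `workers.csv`, `surveys_bodymap.csv`, `surveys_vas.csv` and per-size
#'   layout files, and the in-memory bundle carries the paths. When `NULL`
#'   the bundle is returned in memory only (intended for scaled-down specs).
#' @return List of class `cohort_bundle`: `spec`, `workers` (worker_id,
#'   group, shoe_size, insole), `layouts` (per EU size), `surveys_bodymap`,
#'   `surveys_vas`, `angles[[worker]][[phase]]`,
#'   `insoles[[worker]][[phase]][[side]]`,
#'   `baselines[[worker]][[phase]][[side]]`, and `paths` when written.
#' @export
simulate_cohort <- function(spec = cohort_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, simulate_cohort_impl(spec, out_dir))
}

simulate_cohort_impl <- function(spec, out_dir) {
  nw <- spec$n_workers
  n_prod <- round(nw * spec$fraction_production)
  workers <- data.frame(
    worker_id = sprintf("w%02d", seq_len(nw)),
    group = rep(c("production", "office"), c(n_prod, nw - n_prod)),
    shoe_size = sample(c(39L, 41L, 43L, 45L), nw, replace = TRUE),
    stringsAsFactors = FALSE)
  workers$insole <- workers$group == "production"

  layouts <- lapply(c("39", "41", "43", "45"), simulate_layout)
  names(layouts) <- c("39", "41", "43", "45")

  rho <- spec$phase_correlation
  draw_paired <- function(mu, sdv, d) {
    z <- stats::rnorm(nw)
    e1 <- stats::rnorm(nw); e2 <- stats::rnorm(nw)
    pre <- mu + sdv * (sqrt(rho) * z + sqrt(1 - rho) * e1)
    post <- mu + d * sdv + sdv * (sqrt(rho) * z + sqrt(1 - rho) * e2)
    list(pre = trunc_scale(pre), post = trunc_scale(post))
  }
  exertion <- draw_paired(spec$pre_exertion_mean, spec$exertion_sd, spec$post_shift_d)
  fatigue <- draw_paired(spec$pre_fatigue_mean, spec$fatigue_sd, spec$fatigue_shift_d)

  regions <- body_map_regions()
  grp_off <- c(UE = 0.3, core = 0, LE = -0.5)
  bodymap <- do.call(rbind, lapply(seq_len(nw), function(i) {
    do.call(rbind, lapply(c("pre", "post"), function(ph) {
      base <- exertion[[ph]][i]
      data.frame(worker_id = workers$worker_id[i], phase = ph,
                 region = regions$region,
                 rating = round(trunc_scale(base + grp_off[regions$group] +
                                              stats::rnorm(nrow(regions), 0, 0.7)) * 2) / 2,
                 stringsAsFactors = FALSE)
    }))
  }))
  vas <- do.call(rbind, lapply(c("pre", "post"), function(ph)
    data.frame(worker_id = workers$worker_id, phase = ph,
               vas = round(fatigue[[ph]], 2), stringsAsFactors = FALSE)))

  worker_scale <- spec$base_peak_scale * exp(stats::rnorm(nw, 0, spec$worker_scale_sd))

  angles <- list(); insoles <- list(); baselines <- list()
  for (i in seq_len(nw)) {
    wid <- workers$worker_id[i]
    layout <- layouts[[as.character(workers$shoe_size[i])]]
    angles[[wid]] <- list(); insoles[[wid]] <- list(); baselines[[wid]] <- list()
    for (ph in c("pre", "post")) {
      sess_a <- session(wid, ph, spec$session_s, spec$angle_rate_hz)
      angles[[wid]][[ph]] <- simulate_angles(workers$group[i], spec$session_s,
                                             spec$angle_rate_hz, session = sess_a)
      if (workers$insole[i]) {
        time_fac <- if (ph == "post") 1 + spec$pressure_time_effect else 1
        sess_scale <- worker_scale[i] * time_fac *
          exp(stats::rnorm(1, 0, spec$session_scale_sd))
        side_scale <- c(
          left = sess_scale,
          right = sess_scale * spec$side_asymmetry_ratio *
            exp(stats::rnorm(1, 0, spec$side_noise_sd)))
        insoles[[wid]][[ph]] <- list(); baselines[[wid]][[ph]] <- list()
        for (sd_ in c("left", "right")) {
          sess_p <- session(wid, ph, spec$session_s, spec$pressure_rate_hz)
          base <- simulate_baseline(layout, duration_s = 5,
                                    sample_rate_hz = spec$pressure_rate_hz,
                                    side = sd_, session = sess_p)
          gait <- simulate_gait_pressure(layout, spec$session_s,
                                         spec$pressure_rate_hz, spec$cadence_spm,
                                         peak_scale = side_scale[[sd_]],
                                         side = sd_, session = sess_p)
          # the worn recording includes the lace-binding offsets the
          # baseline was captured to remove
          gait$pressures <- pmin(sweep(gait$pressures, 2L, attr(base, "offsets"), "+"), 64)
          insoles[[wid]][[ph]][[sd_]] <- gait
          baselines[[wid]][[ph]][[sd_]] <- base
        }
      }
    }
  }

  bundle <- structure(list(spec = spec, workers = workers, layouts = layouts,
                           surveys_bodymap = bodymap, surveys_vas = vas,
                           angles = angles, insoles = insoles,
                           baselines = baselines, paths = NULL),
                      class = "cohort_bundle")
  if (!is.null(out_dir)) bundle$paths <- write_cohort(bundle, out_dir)
  bundle
}

# Write a bundle to the on-disk layout run_study() can read back.
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "angles"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "insole"), showWarnings = FALSE)
  paths <- list(root = out_dir)
  data.table::fwrite(bundle$workers, file.path(out_dir, "workers.csv"))
  data.table::fwrite(bundle$surveys_bodymap, file.path(out_dir, "surveys_bodymap.csv"))
  data.table::fwrite(bundle$surveys_vas, file.path(out_dir, "surveys_vas.csv"))
  for (sz in names(bundle$layouts))
    data.table::fwrite(bundle$layouts[[sz]],
                       file.path(out_dir, sprintf("layout_eu%s.csv", sz)))
  for (wid in names(bundle$angles)) {
    for (ph in names(bundle$angles[[wid]])) {
      write_angles(bundle$angles[[wid]][[ph]],
                   file.path(out_dir, "angles", sprintf("%s_%s.csv", wid, ph)))
      if (!is.null(bundle$insoles[[wid]][[ph]])) {
        for (sd_ in names(bundle$insoles[[wid]][[ph]])) {
          write_insole(bundle$insoles[[wid]][[ph]][[sd_]],
                       file.path(out_dir, "insole", sprintf("%s_%s_%s.csv", wid, ph, sd_)))
          write_insole(bundle$baselines[[wid]][[ph]][[sd_]],
                       file.path(out_dir, "insole", sprintf("%s_%s_baseline_%s.csv", wid, ph, sd_)))
        }
      }
    }
  }
  paths
}

#' Read a written cohort bundle back from disk
#'
#' Counterpart of `simulate_cohort(spec, out_dir)`; reconstructs the bundle
#' from the CSV files so the analysis can run on exported data.
#'
#' @param dir Directory written by [simulate_cohort()].
#' @return A `cohort_bundle` (without `spec`).
#' @export
read_cohort <- function(dir) {
  if (!file.exists(file.path(dir, "workers.csv")))
    stop_ergo("%s does not look like a cohort directory (no workers.csv)", dir)
  workers <- as.data.frame(data.table::fread(file.path(dir, "workers.csv")))
  layouts <- list()
  for (sz in c("39", "41", "43", "45")) {
    f <- file.path(dir, sprintf("layout_eu%s.csv", sz))
    if (file.exists(f)) layouts[[sz]] <- as.data.frame(data.table::fread(f))
  }
  angles <- list(); insoles <- list(); baselines <- list()
  for (i in seq_len(nrow(workers))) {
    wid <- workers$worker_id[i]
    angles[[wid]] <- list(); insoles[[wid]] <- list(); baselines[[wid]] <- list()
    layf <- file.path(dir, sprintf("layout_eu%s.csv", workers$shoe_size[i]))
    for (ph in c("pre", "post")) {
      af <- file.path(dir, "angles", sprintf("%s_%s.csv", wid, ph))
      if (file.exists(af)) angles[[wid]][[ph]] <- read_angles(af, worker_id = wid, phase = ph)
      inf <- file.path(dir, "insole", sprintf("%s_%s_left.csv", wid, ph))
      if (file.exists(inf)) {
        insoles[[wid]][[ph]] <- list(); baselines[[wid]][[ph]] <- list()
        for (sd_ in c("left", "right")) {
          insoles[[wid]][[ph]][[sd_]] <- read_insole(
            file.path(dir, "insole", sprintf("%s_%s_%s.csv", wid, ph, sd_)),
            layf, side = sd_, worker_id = wid, phase = ph)
          baselines[[wid]][[ph]][[sd_]] <- read_insole(
            file.path(dir, "insole", sprintf("%s_%s_baseline_%s.csv", wid, ph, sd_)),
            layf, side = sd_, worker_id = wid, phase = ph)
        }
      }
    }
  }
  structure(list(spec = NULL, workers = workers, layouts = layouts,
                 surveys_bodymap = as.data.frame(data.table::fread(file.path(dir, "surveys_bodymap.csv"))),
                 surveys_vas = as.data.frame(data.table::fread(file.path(dir, "surveys_vas.csv"))),
                 angles = angles, insoles = insoles, baselines = baselines,
                 paths = list(root = dir)),
            class = "cohort_bundle")
}
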