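# End-to-end study runner: scores every session, computes plantar pressure
# kinetics, survey composites, and the pre/post and left/right
# repeated-measures comparisons, emitting cohort summary tables analogous to
# a field report (final-score means by phase; loaded-sensor percentages by
# side and phase; per-region impulses by side and phase with signed
# differences) plus the full rmANOVA effect tables.

#' Run the full field-study analysis
#'
#' @param x A `cohort_bundle` from [simulate_cohort()] / [read_cohort()], or
#'   a directory path written by `simulate_cohort(spec, out_dir)`.
#' @param modules Character subset of `c("kinematics", "pressure",
#'   "surveys")`; restricting the set skips the other pipelines (useful when
#'   only one family of effects is of interest).
#' @param load_thresh Loaded-pressure threshold (N/cm^2) passed to
#'   [region_metrics()].
#' @param alpha Significance level used in the effect summaries.
#' @param force A [force_spec()] for RULA scoring.
#' @param thresholds A [cuela_thresholds()] table.
#' @param strict When `TRUE`, a worker with incomplete data aborts the run;
#'   otherwise the worker is skipped with a warning.
#' @return List of class `study_report`:
#' * `table1` - mean and SD of the final RULA and CUELA scores by phase;
#' * `table2` - loaded-sensor percentage by side and phase;
#' * `table3` - per-region impulse by side and phase with post-minus-pre
#'   differences (computed by [region_contrast()] on its own columns);
#' * `survey_summary` - composite and VAS means by phase;
#' * `effects` - named list of [rm_anova()] tables (exertion, fatigue, rula,
#'   cuela, and phase-by-side models for mean/peak pressure, impulse, loaded
#'   time);
#' * `posthoc` - Bonferroni post hoc contrasts for the main comparisons;
#' * `per_worker` - tidy per-worker/phase/side/region metric table;
#' * `log` - character record of every configuration value.
#' @export
run_study <- function(x, modules = c("kinematics", "pressure", "surveys"),
                      load_thresh = 0.6, alpha = 0.05,
                      force = force_spec(), thresholds = cuela_thresholds(),
                      strict = FALSE) {
  if (is.character(x)) x <- read_cohort(x)
  stopifnot(inherits(x, "cohort_bundle"))
  modules <- match.arg(modules, several.ok = TRUE)
  log <- c(sprintf("modules: %s", paste(modules, collapse = ",")),
           sprintf("load_thresh: %g N/cm^2", load_thresh),
           sprintf("alpha: %g", alpha),
           sprintf("force band: %s", force$load_band),
           if (!is.null(x$spec)) sprintf("cohort seed: %d", x$spec$seed))
  workers <- x$workers
  report <- list(log = log)
  skip <- function(msg) {
    if (strict) stop_ergo("%s", msg) else warning(msg, call. = FALSE)
    NULL
  }

  if ("kinematics" %in% modules) {
    rows <- list()
    for (i in seq_len(nrow(workers))) {
      wid <- workers$worker_id[i]
      for (ph in c("pre", "post")) {
        ser <- x$angles[[wid]][[ph]]
        if (is.null(ser)) { skip(sprintf("worker %s lacks %s angle data", wid, ph)); next }
        grand <- rula_score_series(ser, force = force)
        cu <- cuela_score(ser, thresholds)
        dist <- action_level_distribution(grand)
        rows[[length(rows) + 1L]] <- data.frame(
          worker_id = wid, phase = ph,
          rula_final = final_rula_score(grand),
          cuela_final = cu$final_score,
          rula_level1 = dist$proportions[1L], rula_level2 = dist$proportions[2L],
          rula_level3 = dist$proportions[3L], rula_level4 = dist$proportions[4L],
          cuela_green = cu$distribution$proportions[1L],
          cuela_yellow = cu$distribution$proportions[2L],
          cuela_red = cu$distribution$proportions[3L])
      }
    }
    kin <- do.call(rbind, rows)
    # rmANOVA needs a complete paired design; drop workers missing a phase
    tab <- table(kin$worker_id)
    if (any(tab < 2L))
      kin <- kin[!kin$worker_id %in% names(tab)[tab < 2L], , drop = FALSE]
    report$kinematics <- kin
    msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
    report$table1 <- do.call(rbind, lapply(c("RULA", "CUELA"), function(sc) {
      col <- if (sc == "RULA") "rula_final" else "cuela_final"
      do.call(rbind, lapply(c("pre", "post"), function(ph) {
        v <- kin[[col]][kin$phase == ph]
        data.frame(score = sc, phase = ph, mean = mean(v), sd = stats::sd(v))
      }))
    }))
    report$effects$rula <- rm_anova(kin, dv = "rula_final", subject = "worker_id", within = "phase")
    report$effects$cuela <- rm_anova(kin, dv = "cuela_final", subject = "worker_id", within = "phase")
  }

  if ("pressure" %in% modules) {
    rows <- list()
    ins_workers <- workers[workers$insole, , drop = FALSE]
    for (i in seq_len(nrow(ins_workers))) {
      wid <- ins_workers$worker_id[i]
      size <- ins_workers$shoe_size[i]
      for (ph in c("pre", "post")) for (sd_ in c("left", "right")) {
        rec <- x$insoles[[wid]][[ph]][[sd_]]
        base <- x$baselines[[wid]][[ph]][[sd_]]
        if (is.null(rec) || is.null(base)) {
          skip(sprintf("worker %s lacks %s/%s insole data", wid, ph, sd_)); next
        }
        rec <- zero_calibrate(rec, base)
        rec <- exclude_rear_lateral(rec, size)
        masks <- assign_regions(rec)
        rm_ <- region_metrics(rec, masks, load_thresh = load_thresh)
        keep <- setdiff(seq_len(ncol(rec$pressures)), rec$excluded)
        whole <- region_metrics_sensors(rec, keep, load_thresh)
        met <- rbind(cbind(data.frame(region = rm_$region), rm_[-1L]),
                     cbind(data.frame(region = "whole_foot"), whole))
        met$worker_id <- wid; met$phase <- ph; met$side <- sd_
        rows[[length(rows) + 1L]] <- met
      }
    }
    pw <- do.call(rbind, rows)
    whole <- pw[pw$region == "whole_foot", , drop = FALSE]
    tab <- table(whole$worker_id)
    if (any(tab < 4L)) {           # need all phase x side cells per worker
      drop_w <- names(tab)[tab < 4L]
      pw <- pw[!pw$worker_id %in% drop_w, , drop = FALSE]
      whole <- whole[!whole$worker_id %in% drop_w, , drop = FALSE]
    }
    report$per_worker <- pw
    report$table2 <- aggregate_msd(whole, "loaded_sensor_pct", c("phase", "side"))

    imp <- pw[pw$region %in% REGION_NAMES[1:4], , drop = FALSE]
    t3_cells <- stats::aggregate(impulse ~ region + side + phase, imp, mean)
    t3_sd <- stats::aggregate(impulse ~ region + side + phase, imp, stats::sd)
    pre_t <- t3_cells[t3_cells$phase == "pre", c("region", "side", "impulse")]
    post_t <- t3_cells[t3_cells$phase == "post", c("region", "side", "impulse")]
    t3 <- merge(pre_t, post_t, by = c("region", "side"),
                suffixes = c("_pre", "_post"))
    t3 <- merge(t3, stats::setNames(t3_sd[t3_sd$phase == "pre", c("region", "side", "impulse")],
                                    c("region", "side", "impulse_sd_pre")), by = c("region", "side"))
    t3 <- merge(t3, stats::setNames(t3_sd[t3_sd$phase == "post", c("region", "side", "impulse")],
                                    c("region", "side", "impulse_sd_post")), by = c("region", "side"))
    diffs <- do.call(rbind, lapply(split(t3, t3$side), function(d) {
      cd <- region_contrast(
        data.frame(region = d$region, impulse = d$impulse_pre),
        data.frame(region = d$region, impulse = d$impulse_post))
      data.frame(region = cd$region, side = d$side[1L], difference = cd$impulse)
    }))
    t3 <- merge(t3, diffs, by = c("region", "side"))
    report$table3 <- t3[order(t3$region, t3$side), ]

    for (metric in c("mean_pressure", "peak_pressure", "impulse", "loaded_time_fraction")) {
      report$effects[[metric]] <- rm_anova(whole, dv = metric,
                                           subject = "worker_id",
                                           within = c("phase", "side"))
    }
    report$posthoc$mean_pressure_side <- bonferroni_posthoc(
      stats::aggregate(mean_pressure ~ worker_id + side, whole, mean),
      dv = "mean_pressure", subject = "worker_id", within = "side",
      pairs = list(c("left", "right")), alpha = alpha)
    report$posthoc$peak_pressure_side <- bonferroni_posthoc(
      stats::aggregate(peak_pressure ~ worker_id + side, whole, mean),
      dv = "peak_pressure", subject = "worker_id", within = "side",
      pairs = list(c("left", "right")), alpha = alpha)
    report$posthoc$impulse_side <- bonferroni_posthoc(
      stats::aggregate(impulse ~ worker_id + side, whole, mean),
      dv = "impulse", subject = "worker_id", within = "side",
      pairs = list(c("left", "right")), alpha = alpha)
  }

  if ("surveys" %in% modules) {
    bm <- x$surveys_bodymap
    comp <- do.call(rbind, lapply(split(bm, list(bm$worker_id, bm$phase)), function(d) {
      cs <- composite_scores(stats::setNames(d$rating, d$region))
      data.frame(worker_id = d$worker_id[1L], phase = d$phase[1L],
                 total = cs$total, UE = cs$UE, core = cs$core, LE = cs$LE)
    }))
    comp <- merge(comp, x$surveys_vas, by = c("worker_id", "phase"))
    report$surveys <- comp
    report$survey_summary <- do.call(rbind, lapply(c("total", "UE", "core", "LE", "vas"),
      function(cl) aggregate_msd(stats::setNames(comp[c("worker_id", "phase", cl)],
                                                 c("worker_id", "phase", "value")),
                                 "value", "phase", score = cl)))
    report$effects$exertion <- rm_anova(comp, dv = "total", subject = "worker_id", within = "phase")
    report$effects$fatigue <- rm_anova(comp, dv = "vas", subject = "worker_id", within = "phase")
    report$posthoc$exertion_phase <- bonferroni_posthoc(
      comp, dv = "total", subject = "worker_id", within = "phase",
      pairs = list(c("pre", "post")), alpha = alpha)
    report$posthoc$fatigue_phase <- bonferroni_posthoc(
      comp, dv = "vas", subject = "worker_id", within = "phase",
      pairs = list(c("pre", "post")), alpha = alpha)
    report$shapiro <- list(
      exertion_diff = shapiro_screen(
        comp$total[comp$phase == "post"][order(comp$worker_id[comp$phase == "post"])] -
          comp$total[comp$phase == "pre"][order(comp$worker_id[comp$phase == "pre"])]),
      fatigue_diff = shapiro_screen(
        comp$vas[comp$phase == "post"][order(comp$worker_id[comp$phase == "post"])] -
          comp$vas[comp$phase == "pre"][order(comp$worker_id[comp$phase == "pre"])]))
  }

  class(report) <- "study_report"
  report
}

# whole-foot (or any sensor subset) metrics, same definitions as
# region_metrics but over an explicit sensor index set
region_metrics_sensors <- function(recording, idx, load_thresh = 0.6,
                                   persistence = 0.01) {
  p <- recording$pressures[, idx, drop = FALSE]
  dt <- frame_dt(recording)
  nf <- nrow(p)
  loaded <- p >= load_thresh
  n_loaded <- colSums(loaded)
  sens_mean <- ifelse(n_loaded > 0, colSums(p * loaded) / pmax(n_loaded, 1L), 0)
  data.frame(n_sensors = length(idx),
             mean_pressure = mean(sens_mean),
             peak_pressure = mean(apply(p, 2L, max)),
             impulse = mean(colSums(p) * dt),
             loaded_time_fraction = mean(n_loaded / nf),
             loaded_sensor_pct = 100 * mean(n_loaded / nf >= persistence))
}

aggregate_msd <- function(df, col, by, score = NULL) {
  f <- stats::as.formula(paste(col, "~", paste(by, collapse = "+")))
  mu <- stats::aggregate(f, df, mean)
  sdv <- stats::aggregate(f, df, stats::sd)
  out <- mu
  names(out)[names(out) == col] <- "mean"
  out$sd <- sdv[[col]]
  if (!is.null(score)) out <- cbind(data.frame(score = score), out)
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$table1)) {
    cat("\nFinal ergonomic risk scores by phase:\n")
    print(transform(x$table1, mean = round(mean, 2), sd = round(sd, 2)), row.names = FALSE)
  }
  if (!is.null(x$table2)) {
    cat("\nLoaded sensors (% of total) by phase and side:\n")
    print(transform(x$table2, mean = round(mean, 2), sd = round(sd, 2)), row.names = FALSE)
  }
  if (!is.null(x$table3)) {
    cat("\nImpulse (Ns/cm^2) by region and side (post - pre):\n")
    t3 <- x$table3
    t3[vapply(t3, is.numeric, TRUE)] <- lapply(t3[vapply(t3, is.numeric, TRUE)], round, 2)
    print(t3, row.names = FALSE)
  }
  if (length(x$effects)) {
    cat("\nRepeated-measures effects:\n")
    for (nm in names(x$effects)) {
      e <- x$effects[[nm]]
      for (j in seq_len(nrow(e)))
        cat(sprintf("  %-22s %-12s F(%g, %g) = %.3f, p_gg = %.4g, pes = %.3f\n",
                    nm, e$effect[j], e$df_num[j], e$df_den[j], e$F[j],
                    e$p_gg[j], e$partial_eta_sq[j]))
    }
  }
  invisible(x)
}
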