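# CUELA-style zone categorization: each continuous joint-angle channel is
# assigned to green (acceptable), yellow (limited acceptable) or red
# (unacceptable) ranges; the frame zone is the worst channel zone; the final
# score is the zone-weighted time distribution (green=1, yellow=2, red=3),
# which puts it on a 1-3 scale comparable to the RULA final score.
#
# Default angle ranges ship as an editable plain-text file
# (inst/extdata/cuela_thresholds.csv); the DGUV 208-033 instrument that
# inspired them does not publish machine-readable ranges, so the file is the
# authoritative, auditable configuration.

#' Zone thresholds for CUELA categorization
#'
#' Reads a threshold table `channel, green_lo, green_hi, yellow_lo, yellow_hi`
#' (degrees). The green interval must be contained in the yellow interval;
#' anything outside yellow is red. Boundaries are closed on the greener side:
#' an angle exactly on a green/yellow boundary is green.
#'
#' @param path Path to a threshold CSV; default is the packaged file.
#' @return Data frame of class `zone_thresholds`.
#' @export
cuela_thresholds <- function(path = NULL) {
  file <- if (is.null(path))
    system.file("extdata", "cuela_thresholds.csv", package = "ergofield", mustWork = TRUE)
  else path
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("channel", "green_lo", "green_hi", "yellow_lo", "yellow_hi")
  if (!all(need %in% names(df)))
    stop_ergo("threshold file must have columns %s", paste(need, collapse = ", "))
  bad <- with(df, green_lo >= green_hi | yellow_lo > green_lo | yellow_hi < green_hi)
  if (any(bad))
    stop_ergo("invalid threshold rows (green must be inside yellow): %s",
              paste(df$channel[bad], collapse = ", "))
  if (anyDuplicated(df$channel)) stop_ergo("duplicate channels in threshold file")
  class(df) <- c("zone_thresholds", "data.frame")
  df
}

# zone codes: 1 = green, 2 = yellow, 3 = red
zone_of <- function(x, row) {
  ifelse(x >= row$green_lo & x <= row$green_hi, 1L,
  ifelse(x >= row$yellow_lo & x <= row$yellow_hi, 2L, 3L))
}

zone_labels <- function() c("green", "yellow", "red")

# frame x channel matrix of zone codes for all thresholded channels present
zone_matrix <- function(m, thresholds) {
  cont <- setdiff(colnames(m), boolean_angle_channels())
  missing <- setdiff(cont, thresholds$channel)
  if (length(missing))
    stop_ergo("no zone thresholds configured for channel(s): %s",
              paste(missing, collapse = ", "))
  use <- intersect(thresholds$channel, cont)
  z <- matrix(NA_integer_, nrow = nrow(m), ncol = length(use),
              dimnames = list(NULL, use))
  for (ch in use) z[, ch] <- zone_of(m[, ch], thresholds[thresholds$channel == ch, ])
  z
}

#' Categorize one posture frame into CUELA zones
#'
#' @param angles Named numeric vector (or single-row matrix) of joint angles;
#'   every non-boolean channel present must be covered by `thresholds`.
#' @param thresholds A [cuela_thresholds()] table.
#' @return List with `zones` (named per-channel zone labels) and `frame_zone`
#'   (the worst zone across channels, red > yellow > green).
#' @export
cuela_categorize_frame <- function(angles, thresholds = cuela_thresholds()) {
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1L,
                                             dimnames = list(NULL, names(angles)))
  z <- zone_matrix(angles, thresholds)
  labs <- zone_labels()
  list(zones = stats::setNames(labs[z[1L, ]], colnames(z)),
       frame_zone = labs[max(z[1L, ])])
}

#' CUELA zone distribution and final score for a series
#'
#' Computes the per-frame worst-channel zone, the relative time distribution
#' over green/yellow/red, and the distribution-weighted final score
#' `1*p_green + 2*p_yellow + 3*p_red` in `[1, 3]`.
#'
#' @param series A [joint_angle_series()].
#' @param thresholds A [cuela_thresholds()] table.
#' @return Object of class `cuela_result` with elements `distribution` (a
#'   [risk_distribution()] over green/yellow/red) and `final_score`.
#' @export
cuela_score <- function(series, thresholds = cuela_thresholds()) {
  stopifnot(inherits(series, "joint_angle_series"))
  z <- zone_matrix(series$angles, thresholds)
  if (!nrow(z)) stop_ergo("empty series")
  frame_zone <- do.call(pmax, as.data.frame(z))
  p <- tabulate(frame_zone, nbins = 3L) / length(frame_zone)
  structure(list(distribution = risk_distribution(zone_labels(), p),
                 final_score = sum(p * 1:3)),
            class = "cuela_result")
}

#' @export
print.cuela_result <- function(x, ...) {
  cat(sprintf("<cuela_result> final score %.3f (green %.1f%%, yellow %.1f%%, red %.1f%%)\n",
              x$final_score, 100 * x$distribution$proportions[1],
              100 * x$distribution$proportions[2], 100 * x$distribution$proportions[3]))
  invisible(x)
}
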