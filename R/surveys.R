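# Borg CR-10 body-map composites and fatigue VAS handling.
#
# The body map is rated 0-10 per region; composites are unweighted means of
# the regions in each group (upper extremity, core, lower extremity) and the
# total over all regions.

#' Default body-map regions and their group membership
#'
#' A 14-region body map: neck, upper back and lower back form the core group;
#' shoulders, upper arms and forearm/hands the upper-extremity (UE) group;
#' hips, thighs and lower leg/feet the lower-extremity (LE) group. The region
#' list is configurable - only the group semantics are consumed by the
#' analysis.
#'
#' @return Data frame with columns `region`, `group` (`UE`, `core`, `LE`).
#' @export
body_map_regions <- function() {
  data.frame(
    region = c("neck", "upper_back", "lower_back",
               "shoulder_left", "shoulder_right",
               "upper_arm_left", "upper_arm_right",
               "forearm_hand_left", "forearm_hand_right",
               "hips", "thigh_left", "thigh_right",
               "lower_leg_foot_left", "lower_leg_foot_right"),
    group = c("core", "core", "core",
              "UE", "UE", "UE", "UE", "UE", "UE",
              "LE", "LE", "LE", "LE", "LE"),
    stringsAsFactors = FALSE)
}

#' Borg body-map composite scores
#'
#' Computes the total score and the upper-extremity (UE), core and
#' lower-extremity (LE) scores as unweighted means of the group's region
#' ratings.
#'
#' @param ratings Named numeric vector (names = regions) or a data frame with
#'   columns `region`, `rating`; values on the 0-10 CR-10 scale.
#' @param regions Region/group table, defaults to [body_map_regions()].
#' @return Named list `total`, `UE`, `core`, `LE`.
#' @export
composite_scores <- function(ratings, regions = body_map_regions()) {
  if (is.data.frame(ratings))
    ratings <- stats::setNames(ratings$rating, ratings$region)
  missing <- setdiff(regions$region, names(ratings))
  if (length(missing))
    stop_ergo("missing body-map rating(s) for: %s", paste(missing, collapse = ", "))
  r <- ratings[regions$region]
  if (any(!is.finite(r)) || any(r < 0 | r > 10))
    stop_ergo("ratings must lie on the 0-10 scale")
  grp <- split(as.numeric(r), regions$group)
  list(total = mean(r), UE = mean(grp$UE), core = mean(grp$core), LE = mean(grp$LE))
}

#' Classify perceived exertion / fatigue levels
#'
#' Exertion bands on the CR-10 scale: below 2 is low, 2 to 4 (inclusive)
#' moderate, above 4 high. Fatigue bands on the VAS: below 2 low, 2 to 5
#' (inclusive) mild, above 5 high. Band boundaries are closed at the lower
#' edge.
#'
#' @param score Numeric score(s) in `[0, 10]`.
#' @return Character vector of band labels.
#' @export
classify_exertion <- function(score) {
  check_scale(score)
  ifelse(score < 2, "low", ifelse(score <= 4, "moderate", "high"))
}

#' @rdname classify_exertion
#' @export
classify_fatigue <- function(score) {
  check_scale(score)
  ifelse(score < 2, "low", ifelse(score <= 5, "mild", "high"))
}

check_scale <- function(score) {
  if (any(!is.finite(score)) || any(score < 0 | score > 10))
    stop_ergo("scores must lie in [0, 10]")
  invisible(score)
}

#' Fatigue visual-analog-scale value
#'
#' @param value Continuous value in `[0, 10]`.
#' @return Object of class `fatigue_vas`.
#' @export
fatigue_vas <- function(value) {
  check_scale(value)
  structure(list(value = as.numeric(value)), class = "fatigue_vas")
}
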