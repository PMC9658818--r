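#' Gait pattern transition classes
#'
#' The eight locomotion-mode transitions recognised by the pipeline:
#' transitions between level walking and ramp walking and between level
#' walking and stair walking, in both directions. Class ids are the
#' canonical encoding used everywhere in the package (labels, score-matrix
#' columns, mass-function frames).
#'
#' @return A data.frame with columns `id` (integer 1-8), `abbr` and
#'   `description`.
#' @export
#' @examples
#' gait_classes()
gait_classes <- function() {
  data.frame(
    id = 1:8,
    abbr = c("L-R UP", "R-L DOWN", "L-S UP", "S-L DOWN",
             "R-L UP", "L-R DOWN", "S-L UP", "L-S DOWN"),
    description = c(
      "level walking to up-ramp walking transition",
      "down-ramp walking to level walking transition",
      "level walking to up-stair walking transition",
      "down-stair walking to level walking transition",
      "up-ramp walking to level walking transition",
      "level walking to down-ramp walking transition",
      "up-stair walking to level walking transition",
      "level walking to down-stair walking transition"),
    stringsAsFactors = FALSE
  )
}

#' Kinematic channel registry
#'
#' The 22 sagittal-plane lower-limb and coronal-plane trunk kinematic
#' parameters recorded per trial: hip/knee/ankle angular accelerations and
#' velocities for both limbs, segment linear velocities and accelerations,
#' and trunk velocity/acceleration. Channel abbreviations follow the
#' convention `<segment> <quantity>`, e.g. "rt av" = right hip (thigh)
#' angular velocity.
#'
#' @return A data.frame with columns `id` (integer 1-22), `abbr` and
#'   `description`.
#' @export
kinematic_channels <- function() {
  data.frame(
    id = 1:22,
    abbr = c("rt aa", "lt aa", "rs aa", "ls aa", "rf aa", "lf aa",
             "rt av", "lt av", "rs av", "ls av", "rf av", "lf av",
             "ls v", "lt v", "ls a", "lt a", "rt a", "rs a",
             "rt v", "rs v", "trunk a", "trunk v"),
    description = c(
      "right hip angular acceleration",
      "left hip angular acceleration",
      "right knee angular acceleration",
      "left knee angular acceleration",
      "right ankle angular acceleration",
      "left ankle angular acceleration",
      "right hip angular velocity",
      "left hip angular velocity",
      "right knee angular velocity",
      "left knee angular velocity",
      "right ankle angular velocity",
      "left ankle angular velocity",
      "left shank velocity",
      "left thigh velocity",
      "left shank acceleration",
      "left thigh acceleration",
      "right thigh acceleration",
      "right shank acceleration",
      "right thigh velocity",
      "right shank velocity",
      "trunk acceleration",
      "trunk velocity"),
    stringsAsFactors = FALSE
  )
}

# Labels of the 21 per-channel features, in the fixed extraction order:
# 17 time-domain then 4 frequency-domain.
.time_feature_labels <- c(
  "maximum", "minimum", "peak", "peak_to_peak", "mean",
  "average_amplitude", "root_amplitude", "variance", "standard_deviation",
  "rms", "kurtosis", "skewness", "shape_factor", "peak_factor",
  "pulse_factor", "margin_factor", "clearance_factor")

.freq_feature_labels <- c(
  "mean_frequency", "gravity_frequency", "rms_frequency",
  "root_variance_frequency")

#' Per-channel feature labels
#'
#' @param domain Which subset to return: `"all"` (21 labels, time-domain
#'   first), `"time"` (17) or `"freq"` (4).
#' @return Character vector of feature labels.
#' @export
feature_labels <- function(domain = c("all", "time", "freq")) {
  domain <- match.arg(domain)
  switch(domain,
    time = .time_feature_labels,
    freq = .freq_feature_labels,
    all = c(.time_feature_labels, .freq_feature_labels))
}

# Channel abbreviation as used inside composed feature names ("rt av" ->
# "rt_av"); names must be single CSV-safe tokens.
.channel_token <- function(abbr) gsub(" ", "_", abbr, fixed = TRUE)
.token_channel <- function(token) gsub("_", " ", token, fixed = TRUE)

#' Names of the full 462-dimension feature vector
#'
#' Channel-major order: all 21 features of channel 1, then channel 2, and
#' so on. Each name is `<channel_token>.<feature_label>` with spaces in the
#' channel abbreviation replaced by underscores, e.g. `"rt_av.mean"`.
#'
#' @return Character vector of length 462.
#' @export
feature_names <- function() {
  ch <- .channel_token(kinematic_channels()$abbr)
  as.vector(t(outer(ch, feature_labels(), paste, sep = ".")))
}

#' Parse a composed feature name
#'
#' Inverse of the naming used by [feature_names()]: splits
#' `"rt_av.mean"` into the channel abbreviation `"rt av"` and the feature
#' label `"mean"`.
#'
#' @param name Character vector of composed feature names.
#' @return A data.frame with columns `channel_abbr` and `feature_label`.
#' @export
parse_feature_name <- function(name) {
  parts <- regmatches(name, regexpr(".", name, fixed = TRUE), invert = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed feature name(s): ", paste(name[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    channel_abbr = .token_channel(vapply(parts, `[[`, "", 1L)),
    feature_label = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE)
  known_ch <- kinematic_channels()$abbr
  known_lab <- feature_labels()
  bad <- !(out$channel_abbr %in% known_ch) | !(out$feature_label %in% known_lab)
  if (any(bad)) {
    stop("unknown channel or feature label in: ",
         paste(name[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Reference per-class trial counts
#'
#' The per-class sample counts of the benchmark motion-capture dataset the
#' synthetic generator emulates (8 transition classes, 350 trials total).
#' Used as the generator's default class sizes.
#'
#' @return Named integer vector of length 8 (names are class abbreviations).
#' @export
reference_class_counts <- function() {
  stats::setNames(c(45L, 45L, 44L, 42L, 44L, 43L, 44L, 43L),
                  gait_classes()$abbr)
}
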