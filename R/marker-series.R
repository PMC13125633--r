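#' Marker trajectory container
#'
#' `marker_series()` bundles time-indexed 3-D positions of labelled
#' reflective markers with an occlusion mask, the sampling rate and the
#' stream's offset on the shared (SMPTE-style) study clock. Positions are
#' stored in millimetres in an array of dim `c(n_frames, n_markers, 3)`.
#' Occluded entries hold `NA` coordinates and `TRUE` in the mask; no `NA`
#' is allowed outside the mask.
#'
#' @param positions numeric array, dim `c(n_frames, n_markers, 3)` (mm).
#' @param labels character vector of marker names, length `n_markers`.
#' @param rate sampling frequency in Hz (> 0).
#' @param occluded logical matrix `n_frames x n_markers`; default: marks
#'   entries whose coordinates contain `NA`.
#' @param start_time offset of frame 1 on the shared clock, seconds.
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(positions, labels, rate, occluded = NULL,
                          start_time = 0) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 3)
  if (length(labels) != dim(positions)[2]) {
    stop("length(labels) must equal the number of markers")
  }
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (is.null(occluded)) {
    occluded <- apply(is.na(positions), c(1, 2), any)
    if (!is.matrix(occluded)) occluded <- matrix(occluded, dim(positions)[1])
  }
  stopifnot(is.logical(occluded),
            nrow(occluded) == dim(positions)[1],
            ncol(occluded) == dim(positions)[2])
  # no NaN/NA outside occluded entries
  bad <- apply(is.na(positions), c(1, 2), any) & !occluded
  if (any(bad)) stop("NA positions found outside the occlusion mask")
  positions[is.nan(positions)] <- NA_real_
  dimnames(positions) <- list(NULL, labels, c("x", "y", "z"))
  structure(list(labels = as.character(labels),
                 positions = positions,
                 rate = rate,
                 occluded = occluded,
                 start_time = start_time),
            class = "marker_series")
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %d frames x %d markers @ %g Hz, start %.3f s\n",
              n_frames(x), length(x$labels), x$rate, x$start_time))
  cat(sprintf("  occluded entries: %d (%.2f%%)\n", sum(x$occluded),
              100 * mean(x$occluded)))
  cat("  markers:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marker_series <- function(x) dim(x$positions)

#' Number of frames of a marker series
#' @param x a `marker_series`.
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$positions)[1]

#' Frame timestamps of a marker series
#' @param x a `marker_series`.
#' @return numeric vector `start_time + (0:(n-1))/rate` in seconds.
#' @export
frame_times <- function(x) x$start_time + (seq_len(n_frames(x)) - 1) / x$rate

#' Extract one marker's trajectory
#' @param x a `marker_series`.
#' @param label marker name.
#' @return `n_frames x 3` matrix (mm), `NA` where occluded.
#' @export
marker_xyz <- function(x, label) {
  i <- match(label, x$labels)
  if (is.na(i)) stop(sprintf("marker '%s' not present in series", label))
  m <- x$positions[, i, , drop = FALSE]
  dim(m) <- c(dim(x$positions)[1], 3)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Trial metadata
#'
#' Identifies one trial of the mixed between-within design: participant,
#' training group, exercise and measurement stage.
#'
#' @param participant_id integer 1-24.
#' @param group `"AV"` (control) or `"AVE"` (haptic exoskeleton).
#' @param exercise 1, 2 or 3.
#' @param stage `"S1"` (baseline), `"S2"` (training) or `"S3"` (recall).
#' @return an object of class `trial_meta`.
#' @export
trial_meta <- function(participant_id, group, exercise, stage) {
  group <- match.arg(group, c("AV", "AVE"))
  stage <- match.arg(stage, c("S1", "S2", "S3"))
  if (!exercise %in% 1:3) stop("exercise must be 1, 2 or 3")
  participant_id <- as.integer(participant_id)
  if (is.na(participant_id) || participant_id < 1 || participant_id > 24) {
    stop("participant_id must be an integer in 1..24")
  }
  structure(list(participant_id = participant_id, group = group,
                 exercise = as.integer(exercise), stage = stage),
            class = "trial_meta")
}
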