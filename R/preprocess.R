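# Marker-stream cleaning: occlusion gap filling, zero-phase low-pass
# filtering and clock alignment of paired streams.

# run-length encode a logical vector into (start, length) of TRUE runs
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Fill short occlusion gaps by cubic-spline interpolation
#'
#' Occluded runs of length `max_gap` or shorter are replaced, per
#' coordinate, by a cubic spline fitted to the marker's visible samples;
#' the filled entries are unflagged. Longer runs are left occluded. Gaps
#' touching the sequence edge are filled by the spline's boundary
#' extrapolation, again only when the run is short enough. Visible samples
#' are never modified.
#'
#' @param series a [marker_series()].
#' @param max_gap maximum run length (frames) that will be filled; >= 0.
#' @return a [marker_series()] with short gaps filled.
#' @export
fill_gaps <- function(series, max_gap = 10) {
  stopifnot(max_gap >= 0)
  pos <- series$positions
  occ <- series$occluded
  nf <- nrow(occ)
  for (k in seq_along(series$labels)) {
    col <- occ[, k]
    if (!any(col)) next
    if (all(col)) {
      warning(sprintf("marker '%s' occluded for the entire trial; left untouched",
                      series$labels[k]))
      next
    }
    runs <- true_runs(col)
    runs <- runs[runs$length <= max_gap, , drop = FALSE]
    if (nrow(runs) == 0) next
    good <- which(!col)
    for (d in 1:3) {
      sf <- stats::splinefun(good, pos[good, k, d], method = "natural")
      for (r in seq_len(nrow(runs))) {
        idx <- runs$start[r]:(runs$start[r] + runs$length[r] - 1)
        pos[idx, k, d] <- sf(idx)
      }
    }
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r]:(runs$start[r] + runs$length[r] - 1)
      occ[idx, k] <- FALSE
    }
  }
  marker_series(pos, series$labels, series$rate, occ, series$start_time)
}

#' Zero-phase low-pass filter a marker series
#'
#' Applies a 4th-order Butterworth low-pass, forward and backward
#' (zero phase), to every coordinate of every marker. The DC component is
#' preserved. All occlusions must have been filled first.
#'
#' @param series a [marker_series()] without occluded entries.
#' @param cutoff cutoff frequency in Hz, `0 < cutoff < rate/2`. The 10 Hz
#'   default is standard practice for upper-limb movement data.
#' @return filtered [marker_series()].
#' @export
lowpass <- function(series, cutoff = 10) {
  if (cutoff <= 0 || cutoff >= series$rate / 2) {
    stop(sprintf("cutoff must lie in (0, %g) Hz", series$rate / 2))
  }
  if (any(series$occluded)) {
    stop("series still contains occluded entries; run fill_gaps() first")
  }
  pos <- series$positions
  for (k in seq_along(series$labels)) {
    for (d in 1:3) {
      pos[, k, d] <- lowpass_vec(pos[, k, d], series$rate, cutoff)
    }
  }
  marker_series(pos, series$labels, series$rate, series$occluded,
                series$start_time)
}

# zero-phase low-pass for a plain numeric vector: forward-backward passes
# of a 2nd-order Butterworth (4th-order magnitude response), with odd
# reflection padding at both ends so start-up transients decay inside the
# padding and the DC level is preserved
lowpass_vec <- function(x, rate, cutoff) {
  n <- length(x)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  pad <- min(n - 1, ceiling(3 * rate / cutoff))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  run <- function(v) {
    # reference the filter state to the first sample: a constant input
    # passes through exactly (DC gain 1, no start-up transient)
    c0 <- v[1]
    as.numeric(signal::filter(bf, v - c0)) + c0
  }
  y <- rev(run(rev(run(xp))))
  y[(pad + 1):(pad + n)]
}

#' Crop two marker streams to their common clock window
#'
#' Both streams carry `start_time` on the shared (SMPTE-style) study
#' clock and must have equal sampling rates. The outputs cover the
#' overlapping window only, frame i of each corresponding to the same
#' clock time within half a frame (nearest-frame alignment, no sub-frame
#' resampling).
#'
#' @param a,b [marker_series()] objects with equal `rate`.
#' @return list with elements `a` and `b`, cropped.
#' @export
align_pair <- function(a, b) {
  if (abs(a$rate - b$rate) > 1e-9) stop("align_pair requires equal rates")
  t0 <- max(a$start_time, b$start_time)
  t1 <- min(a$start_time + (n_frames(a) - 1) / a$rate,
            b$start_time + (n_frames(b) - 1) / b$rate)
  if (t1 < t0 - 1e-12) stop("streams do not overlap in time")
  crop <- function(s) {
    i0 <- round((t0 - s$start_time) * s$rate) + 1
    i1 <- round((t1 - s$start_time) * s$rate) + 1
    idx <- i0:i1
    marker_series(s$positions[idx, , , drop = FALSE], s$labels, s$rate,
                  s$occluded[idx, , drop = FALSE],
                  start_time = s$start_time + (i0 - 1) / s$rate)
  }
  ca <- crop(a)
  cb <- crop(b)
  n <- min(n_frames(ca), n_frames(cb))
  if (n < 1) stop("streams do not overlap in time")
  trim <- function(s) {
    marker_series(s$positions[seq_len(n), , , drop = FALSE], s$labels, s$rate,
                  s$occluded[seq_len(n), , drop = FALSE], s$start_time)
  }
  list(a = trim(ca), b = trim(cb))
}
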