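# Bowing-stroke detection and bookkeeping: direction changes with
# hysteresis, stroke segmentation, bow-half masks and time-normalized
# per-stroke profiles.

#' Detect bowing direction changes
#'
#' Finds reversal times of the bow coordinate `b(t)` with a
#' turning-points (hysteresis) rule: a candidate reversal is kept only if
#' `b` moves at least `min_excursion` bow-lengths on both sides of it,
#' and at least `min_interval` seconds separate kept events (the later
#' candidate is dropped). Event times are refined by linear interpolation
#' to the zero crossing of the bow velocity `v`. The defaults reject
#' tremor-scale ripple at novice bowing tempi; the study itself does not
#' prescribe a detector.
#'
#' @param trace a bow trace (see [bow_trace()]).
#' @param min_excursion minimum excursion on both sides, bow-lengths
#'   (default 0.05).
#' @param min_interval minimum time between kept events, s (default 0.25).
#' @return numeric vector of event times in seconds (relative to the
#'   first frame of the trace). Empty when the motion is monotone.
#' @export
detect_direction_changes <- function(trace, min_excursion = 0.05,
                                     min_interval = 0.25) {
  b <- trace$b
  n <- length(b)
  if (n == 0) stop("empty bow trace")
  # turning-points scan with hysteresis on both sides
  events <- integer()
  ext_hi <- b[1]; i_hi <- 1L   # running maximum since the last reversal
  ext_lo <- b[1]; i_lo <- 1L   # running minimum since the last reversal
  dir <- 0L                    # +1 rising, -1 falling, 0 unknown
  for (i in 2:n) {
    if (b[i] > ext_hi) { ext_hi <- b[i]; i_hi <- i }
    if (b[i] < ext_lo) { ext_lo <- b[i]; i_lo <- i }
    if (dir == 0L) {
      if (b[i] - ext_lo >= min_excursion) {
        dir <- 1L; ext_hi <- b[i]; i_hi <- i
      } else if (ext_hi - b[i] >= min_excursion) {
        dir <- -1L; ext_lo <- b[i]; i_lo <- i
      }
    } else if (dir == 1L && ext_hi - b[i] >= min_excursion) {
      events <- c(events, i_hi)
      dir <- -1L; ext_lo <- b[i]; i_lo <- i
    } else if (dir == -1L && b[i] - ext_lo >= min_excursion) {
      events <- c(events, i_lo)
      dir <- 1L; ext_hi <- b[i]; i_hi <- i
    }
  }
  if (length(events) == 0) {
    warning("fewer than 2 direction changes detected; stroke list will be empty")
    return(numeric())
  }
  times <- vapply(events, function(i) reversal_time(trace, i), 0)
  if (length(times) > 1) {
    keep <- times[1]
    for (t in times[-1]) {
      if (t - keep[length(keep)] >= min_interval) keep <- c(keep, t)
    }
    times <- keep
  }
  if (length(times) < 2) {
    warning("fewer than 2 direction changes detected; stroke list will be empty")
  }
  times
}

# refine a reversal at frame index i to the linear zero crossing of v
reversal_time <- function(trace, i) {
  v <- trace$v
  n <- length(v)
  t_of <- function(j) (j - 1) / trace$rate
  for (j in max(2, i - 1):min(n - 1, i + 1)) {
    if (v[j] == 0) return(t_of(j))
    if (v[j] * v[j + 1] < 0) {
      frac <- v[j] / (v[j] - v[j + 1])
      return(t_of(j) + frac / trace$rate)
    }
  }
  t_of(i)
}

#' Segment a bow trace into strokes
#'
#' Strokes span consecutive event times; the leading and trailing partial
#' segments (before the first and after the last event) are discarded
#' unless `include_ends = TRUE`, in which case an end segment is kept
#' when its bow excursion reaches `min_excursion`. Direction is `"down"`
#' when `b` increases over the stroke (frog to tip), `"up"` otherwise.
#'
#' @param trace a bow trace.
#' @param events sorted event times (s), e.g. from
#'   [detect_direction_changes()].
#' @param include_ends keep sufficiently large end segments as strokes.
#' @param min_excursion excursion needed for an end segment to count.
#' @return data.frame with columns `i_start`, `i_end` (half-open frame
#'   range), `direction`, `b_min`, `b_max`, `t_start`, `t_end`.
#' @export
segment_strokes <- function(trace, events, include_ends = FALSE,
                            min_excursion = 0.05) {
  n <- length(trace$b)
  if (length(events) == 0 && !include_ends) {
    return(empty_stroke_table())
  }
  idx <- round(events * trace$rate) + 1
  idx <- pmin(pmax(idx, 1), n)
  bounds <- idx
  if (include_ends) {
    if (length(idx) == 0) {
      if (diff(range(trace$b)) >= min_excursion) bounds <- c(1L, n)
    } else {
      if (idx[1] > 1 &&
          diff(range(trace$b[1:idx[1]])) >= min_excursion) {
        bounds <- c(1L, bounds)
      }
      last <- idx[length(idx)]
      if (last < n && diff(range(trace$b[last:n])) >= min_excursion) {
        bounds <- c(bounds, n)
      }
    }
  }
  bounds <- sort(unique(bounds))
  if (length(bounds) < 2) return(empty_stroke_table())
  out <- lapply(seq_len(length(bounds) - 1), function(k) {
    i0 <- bounds[k]
    i1 <- bounds[k + 1]
    bs <- trace$b[i0:i1]
    data.frame(i_start = i0, i_end = i1,
               direction = if (bs[length(bs)] >= bs[1]) "down" else "up",
               b_min = min(bs), b_max = max(bs),
               t_start = (i0 - 1) / trace$rate,
               t_end = (i1 - 1) / trace$rate)
  })
  do.call(rbind, out)
}

empty_stroke_table <- function() {
  data.frame(i_start = integer(), i_end = integer(), direction = character(),
             b_min = numeric(), b_max = numeric(), t_start = numeric(),
             t_end = numeric())
}

#' Upper/lower bow-half frame masks
#'
#' The upper half is the tip half (`b > 0.5`); the boundary sample
#' `b == 0.5` is assigned to the lower half. The two masks partition the
#' frames.
#'
#' @param trace a bow trace.
#' @return list with logical vectors `upper` and `lower`.
#' @export
half_masks <- function(trace) {
  upper <- trace$b > 0.5
  list(upper = upper, lower = !upper)
}

#' Time-normalized per-stroke profiles
#'
#' Linearly resamples a per-frame channel onto `n_points` equally spaced
#' points of normalized stroke time (0-100%). Strokes shorter than 4
#' frames are skipped with a warning.
#'
#' @param channel numeric per-frame vector (angle in deg, or `b`).
#' @param strokes stroke table from [segment_strokes()].
#' @param n_points resample count; 101 (1% steps) is the biomechanics
#'   convention.
#' @return matrix `n_strokes_kept x n_points`; attribute `kept` holds the
#'   row indices of the strokes retained.
#' @export
normalize_profiles <- function(channel, strokes, n_points = 101) {
  keep <- which(strokes$i_end - strokes$i_start + 1 >= 4)
  if (length(keep) < nrow(strokes)) {
    warning(sprintf("%d stroke(s) shorter than 4 frames skipped",
                    nrow(strokes) - length(keep)))
  }
  out <- matrix(NA_real_, length(keep), n_points)
  for (r in seq_along(keep)) {
    s <- strokes[keep[r], ]
    idx <- s$i_start:s$i_end
    out[r, ] <- stats::approx(seq_along(idx), channel[idx],
                              xout = seq(1, length(idx), length.out = n_points))$y
  }
  attr(out, "kept") <- keep
  out
}

#' Classify a stroke's bow extent
#'
#' Groups strokes into `"full"`, `"upper"` (tip-half) and `"lower"`
#' (frog-half) classes from the bow interval they cover, so that
#' variability is measured across repeats of the same figure rather than
#' across different figures.
#'
#' @param b_min,b_max bow interval covered by the stroke.
#' @param full_span minimum span counted as a full bow (default 0.6).
#' @return character class.
#' @export
classify_extent <- function(b_min, b_max, full_span = 0.6) {
  span <- b_max - b_min
  ifelse(span >= full_span, "full",
         ifelse((b_min + b_max) / 2 > 0.5, "upper", "lower"))
}
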