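# The seventeen per-trial performance metrics.
#
#   m1  full bow range used (bow-length fraction)
#   m2  ROM elbow FE (deg)                    m3  ROM shoulder AA (deg)
#   m4/m5   elbow-FE : shoulder-AA ROM ratio, upper / lower bow half
#   m6/m7   shoulder-AA ROM : bow portion, upper / lower half
#   m8/m9   elbow-FE ROM : bow portion, upper / lower half
#   m10/m11 across-stroke variability of elbow FE / shoulder AA (deg)
#   m12 coordination (vector-coding coupling angle) variability (deg)
#   m13 signed summed timing difference of bowing reversals (s)
#   m14 RMS distance of bow position to the teacher's (percent of bow)
#   m15 SPARC smoothness (negative, dimensionless)
#   m16 synchronization strength (mean resultant length, [0, 1])
#   m17 phase shift (circular mean relative phase, rad, [-pi, pi))
#
# An undefined metric is an explicit NA marker; it is never zero-filled
# and is excluded pairwise from downstream statistics.

METRIC_IDS <- paste0("m", 1:17)

#' Range of motion
#'
#' Max minus min of a channel over the unmasked frames; the standard ROM
#' measure, computed on the filtered signal.
#'
#' @param channel numeric per-frame values.
#' @param mask optional logical frame mask (`TRUE` = use frame).
#' @return ROM in the channel's units, or `NA` when fewer than 2 frames
#'   remain.
#' @export
rom <- function(channel, mask = NULL) {
  x <- if (is.null(mask)) channel else channel[mask]
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  max(x) - min(x)
}

#' Spatial metric block (m1-m9)
#'
#' ROMs and mask-restricted ROM ratios of elbow FE, shoulder AA and the
#' bow coordinate, computed over the whole exercise with the upper/lower
#' bow-half masks. A ratio whose denominator ROM is below `1e-6` yields
#' an undefined (NA) marker.
#'
#' @param angles a [joint_angle_series()].
#' @param trace a bow trace aligned with `angles`.
#' @param masks half masks from [half_masks()].
#' @return named numeric vector `m1`..`m9`.
#' @export
spatial_block <- function(angles, trace, masks = half_masks(trace)) {
  safe_ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || den < 1e-6) NA_real_ else num / den
  }
  up <- masks$upper
  lo <- masks$lower
  b <- trace$b
  fe <- angles$elbow_fe
  aa <- angles$shoulder_aa
  c(m1 = rom(b),
    m2 = rom(fe),
    m3 = rom(aa),
    m4 = safe_ratio(rom(fe, up), rom(aa, up)),
    m5 = safe_ratio(rom(fe, lo), rom(aa, lo)),
    m6 = safe_ratio(rom(aa, up), rom(b, up)),
    m7 = safe_ratio(rom(aa, lo), rom(b, lo)),
    m8 = safe_ratio(rom(fe, up), rom(b, up)),
    m9 = safe_ratio(rom(fe, lo), rom(b, lo)))
}

#' Across-stroke variability of a profile set
#'
#' At each normalized-time point, the sample SD (n-1 denominator) across
#' strokes; the metric is the mean SD over the points.
#'
#' @param profiles matrix `n_strokes x n_points` from
#'   [normalize_profiles()].
#' @return mean SD (same units as the channel), `NA` with fewer than 2
#'   profiles.
#' @export
variability <- function(profiles) {
  if (is.null(dim(profiles)) || nrow(profiles) < 2) return(NA_real_)
  mean(apply(profiles, 2, stats::sd))
}

#' Vector-coding coordination variability
#'
#' For each stroke and each adjacent pair of normalized-time points, the
#' coupling angle `gamma = atan2(d shoulder_aa, d elbow_fe)` is computed
#' (vector coding). At each step the circular SD of the coupling angles
#' across strokes is taken; the metric is the mean over steps. Strokes
#' with no motion in either joint at a step are skipped for that step.
#'
#' @param elbow_profiles,shoulder_profiles matched profile matrices
#'   (`n_strokes x n_points`).
#' @param trim fraction of steps discarded at each end of the stroke:
#'   around a bow reversal both joints are nearly still and the coupling
#'   angle is undefined, so the reversal neighborhoods are excluded.
#' @param min_motion minimum joint-space increment magnitude (deg per
#'   step) for a stroke to contribute at a step; below it the coupling
#'   angle is dominated by noise.
#' @return mean circular SD in degrees, `NA` with fewer than 2 strokes.
#' @export
coordination_variability <- function(elbow_profiles, shoulder_profiles,
                                     trim = 0.08, min_motion = 0.05) {
  if (is.null(dim(elbow_profiles)) || nrow(elbow_profiles) < 2) return(NA_real_)
  stopifnot(all(dim(elbow_profiles) == dim(shoulder_profiles)))
  de <- t(diff(t(elbow_profiles)))
  ds <- t(diff(t(shoulder_profiles)))
  n_steps <- ncol(de)
  steps <- seq_len(n_steps)
  if (trim > 0) {
    lo <- ceiling(trim * n_steps) + 1
    hi <- floor((1 - trim) * n_steps)
    steps <- steps[steps >= lo & steps <= hi]
  }
  sds <- rep(NA_real_, n_steps)
  for (j in steps) {
    mag <- sqrt(de[, j]^2 + ds[, j]^2)
    ok <- mag >= min_motion & mag > 0
    if (sum(ok) < 2) next
    gamma <- atan2(ds[ok, j], de[ok, j])
    sds[j] <- circ_sd_deg(gamma)
  }
  if (all(is.na(sds))) return(NA_real_)
  mean(sds, na.rm = TRUE)
}

#' Signed summed timing difference between event trains
#'
#' Greedily matches each teacher reversal to the nearest unmatched
#' participant reversal (ascending absolute difference, one-to-one) and
#' sums the signed differences (participant minus teacher) over matched
#' pairs, capturing cumulative drift over the exercise. Unmatched events
#' are ignored but counted in the `unmatched` attribute for QC.
#'
#' @param events_p,events_t sorted participant / teacher event times (s).
#' @return signed sum in seconds with attribute `unmatched`, or `NA`
#'   when either train is empty.
#' @export
timing_difference <- function(events_p, events_t) {
  if (length(events_p) == 0 || length(events_t) == 0) return(NA_real_)
  pairs <- expand.grid(p = seq_along(events_p), t = seq_along(events_t))
  pairs$d <- abs(events_p[pairs$p] - events_t[pairs$t])
  pairs <- pairs[order(pairs$d), ]
  used_p <- logical(length(events_p))
  used_t <- logical(length(events_t))
  total <- 0
  n_matched <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$p[r]; j <- pairs$t[r]
    if (used_p[i] || used_t[j]) next
    used_p[i] <- TRUE
    used_t[j] <- TRUE
    total <- total + (events_p[i] - events_t[j])
    n_matched <- n_matched + 1L
  }
  structure(total,
            unmatched = (length(events_p) - n_matched) +
              (length(events_t) - n_matched))
}

#' RMS distance between two aligned bow traces
#'
#' `100 * sqrt(mean((b_p - b_t)^2))`: the root-mean-square difference of
#' normalized bow position, expressed as percent of bow length.
#'
#' @param trace_p,trace_t aligned bow traces of equal length.
#' @return RMS distance (percent of bow length).
#' @export
euclidean_distance <- function(trace_p, trace_t) {
  if (length(trace_p$b) != length(trace_t$b)) {
    stop("bow traces must be aligned to equal length")
  }
  100 * sqrt(mean((trace_p$b - trace_t$b)^2))
}

#' Event-based synchronization strength and phase shift
#'
#' For each teacher inter-event interval `[t_k, t_{k+1})`, the
#' participant event nearest to `t_k` defines the relative phase
#' `phi_k = 2*pi*(t_p - t_k)/(t_{k+1} - t_k)`, wrapped to `[-pi, pi)`.
#' The synchronization strength is the mean resultant length of the
#' phases; the phase shift is their circular mean.
#'
#' @param events_p,events_t sorted participant / teacher event times (s);
#'   at least 3 teacher events are required.
#' @return list with `strength` (in [0, 1]) and `phase` (rad); both `NA`
#'   when fewer than 2 teacher intervals or no participant events exist.
#' @export
synchronization <- function(events_p, events_t) {
  if (length(events_t) < 3 || length(events_p) == 0) {
    return(list(strength = NA_real_, phase = NA_real_))
  }
  phases <- vapply(seq_len(length(events_t) - 1), function(k) {
    tk <- events_t[k]
    tp <- events_p[which.min(abs(events_p - tk))]
    wrap_pi(2 * pi * (tp - tk) / (events_t[k + 1] - events_t[k]))
  }, 0)
  res <- circ_resultant(phases)
  list(strength = res$rbar, phase = wrap_pi(res$mean))
}

#' Compute the full 17-metric vector for one trial
#'
#' Delegates to the individual metric operations: spatial block on the
#' participant's kinematics, variability metrics on per-stroke profiles
#' grouped by direction and bow-extent class (so repeats of the same
#' figure are compared), timing/synchronization on the reversal-event
#' trains of participant versus teacher, RMS bow distance on the aligned
#' traces and per-stroke SPARC on the participant's bow speed. Undefined
#' metrics propagate as NA markers and are never imputed.
#'
#' @param participant,teacher lists with elements `angles` (a
#'   [joint_angle_series()]) and `trace` (a bow trace), time-aligned.
#' @param meta optional [trial_meta()] attached to the result.
#' @param min_excursion,min_interval reversal-detection thresholds, see
#'   [detect_direction_changes()].
#' @param sparc_par SPARC parameters, see [sparc_params()].
#' @param n_points profile resample count.
#' @return named numeric vector `m1`..`m17` with attributes `qc` (stroke
#'   counts, unmatched events, clip rate) and `meta`.
#' @export
compute_all <- function(participant, teacher, meta = NULL,
                        min_excursion = 0.05, min_interval = 0.25,
                        sparc_par = sparc_params(), n_points = 101) {
  tr_p <- participant$trace
  tr_t <- teacher$trace
  ev_p <- suppressWarnings(detect_direction_changes(tr_p, min_excursion,
                                                    min_interval))
  ev_t <- suppressWarnings(detect_direction_changes(tr_t, min_excursion,
                                                    min_interval))
  strokes_p <- segment_strokes(tr_p, ev_p, include_ends = TRUE,
                               min_excursion = min_excursion)

  out <- stats::setNames(rep(NA_real_, 17), METRIC_IDS)
  out[1:9] <- spatial_block(participant$angles, tr_p)

  if (nrow(strokes_p) >= 2) {
    grp <- paste(strokes_p$direction,
                 classify_extent(strokes_p$b_min, strokes_p$b_max))
    prof_e <- suppressWarnings(
      normalize_profiles(participant$angles$elbow_fe, strokes_p, n_points))
    prof_s <- suppressWarnings(
      normalize_profiles(participant$angles$shoulder_aa, strokes_p, n_points))
    kept <- attr(prof_e, "kept")
    grp <- grp[kept]
    m10g <- m11g <- m12g <- numeric()
    wts <- numeric()
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (length(rows) < 2) next
      m10g <- c(m10g, variability(prof_e[rows, , drop = FALSE]))
      m11g <- c(m11g, variability(prof_s[rows, , drop = FALSE]))
      m12g <- c(m12g, coordination_variability(prof_e[rows, , drop = FALSE],
                                               prof_s[rows, , drop = FALSE]))
      wts <- c(wts, length(rows))
    }
    if (length(wts) > 0) {
      out["m10"] <- stats::weighted.mean(m10g, wts, na.rm = TRUE)
      out["m11"] <- stats::weighted.mean(m11g, wts, na.rm = TRUE)
      out["m12"] <- stats::weighted.mean(m12g, wts, na.rm = TRUE)
    }
  }

  td <- timing_difference(ev_p, ev_t)
  out["m13"] <- as.numeric(td)
  out["m14"] <- euclidean_distance(tr_p, tr_t)
  out["m15"] <- sparc_trial(tr_p, strokes_p, sparc_par)
  sy <- synchronization(ev_p, ev_t)
  out["m16"] <- sy$strength
  out["m17"] <- sy$phase

  attr(out, "qc") <- list(n_strokes = nrow(strokes_p),
                          n_events_p = length(ev_p),
                          n_events_t = length(ev_t),
                          unmatched_events = attr(td, "unmatched") %||% NA,
                          clip_rate = tr_p$clip_rate)
  attr(out, "meta") <- meta
  out
}

#' Export metric vectors as a tidy table
#'
#' @param metrics named list of metric vectors (one per trial), each with
#'   a `meta` attribute.
#' @return data.frame with one row per metric per trial: `participant`,
#'   `group`, `exercise`, `stage`, `metric_id`, `value`, `defined_flag`.
#' @export
metrics_to_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(mv) {
    meta <- attr(mv, "meta")
    data.frame(participant = meta$participant_id, group = meta$group,
               exercise = meta$exercise, stage = meta$stage,
               metric_id = METRIC_IDS, value = as.numeric(mv),
               defined_flag = !is.na(as.numeric(mv)))
  }))
}
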