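# Synthetic study generator: scripted exercises, teacher reference
# trajectories, learner deviation models, viscous-elastic haptic guidance
# and forward-kinematic marker emission.
#
# The generator is first-class, tested code: it provides ground truth for
# every pipeline stage. Its defaults encode the study conditions (three
# exercises, 120 Hz, 12 participants per group, 5 raters); deviation
# magnitudes are documented modelling choices.

#' Exercise stroke scripts
#'
#' The three training exercises:
#' \itemize{
#'   \item exercise 1: four full-bow down-up pairs on the G string
#'     (8 strokes);
#'   \item exercise 2: two repeats of the six-stroke pattern full down,
#'     half up, half down, full up, half down, half up (12 strokes);
#'   \item exercise 3: four full-bow down-up pairs alternating between
#'     the G and D strings (8 strokes).
#' }
#' Full bows span b = 0.1 to 0.9; half bows span half that range, with
#' the bow-coordinate waypoints following from stroke-to-stroke
#' continuity.
#'
#' @param exercise_id 1, 2 or 3.
#' @param tempo stroke duration in seconds (default 1.5, a comfortable
#'   novice full-bow tempo).
#' @param repeats repetition count of the base pattern (defaults: 4, 2,
#'   4 as in the study protocol).
#' @return object of class `exercise_script`: list with `exercise_id`,
#'   `tempo`, `waypoints` (b at stroke boundaries), `strings` (per
#'   stroke), `directions`, `n_strokes`.
#' @export
exercise_script <- function(exercise_id, tempo = 1.5, repeats = NULL) {
  if (!exercise_id %in% 1:3) stop("exercise_id must be 1, 2 or 3")
  b_lo <- 0.1
  b_hi <- 0.9
  half <- (b_lo + b_hi) / 2
  if (exercise_id == 1) {
    repeats <- repeats %||% 4L
    ext <- rep(c("full", "full"), repeats)
    strings <- rep("G", 2 * repeats)
  } else if (exercise_id == 2) {
    repeats <- repeats %||% 2L
    ext <- rep(c("full", "half", "half", "full", "half", "half"), repeats)
    strings <- rep("G", 6 * repeats)
  } else {
    repeats <- repeats %||% 4L
    ext <- rep(c("full", "full"), repeats)
    strings <- rep(c("G", "D"), repeats)
  }
  n <- length(ext)
  directions <- rep(c("down", "up"), length.out = n)
  wp <- numeric(n + 1)
  wp[1] <- b_lo
  for (k in seq_len(n)) {
    step <- if (ext[k] == "full") (b_hi - b_lo) else (b_hi - b_lo) / 2
    wp[k + 1] <- wp[k] + if (directions[k] == "down") step else -step
  }
  if (any(wp < b_lo - 1e-9 | wp > b_hi + 1e-9)) {
    stop("internal error: stroke plan leaves the bow range")  # nocov
  }
  structure(list(exercise_id = as.integer(exercise_id), tempo = tempo,
                 waypoints = wp, extents = ext, strings = strings,
                 directions = directions, n_strokes = n),
            class = "exercise_script")
}

#' @export
print.exercise_script <- function(x, ...) {
  cat(sprintf("<exercise_script> exercise %d: %d strokes @ %.2f s/stroke\n",
              x$exercise_id, x$n_strokes, x$tempo))
  invisible(x)
}

# minimum-jerk unit profile on [0, 1]
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# piecewise minimum-jerk bow coordinate through (event_times, waypoints).
# A small tapered sinusoidal speed texture (3 cycles per stroke, 3% of the
# stroke extent) rides on each stroke: real bowing strokes are not single
# perfect submovements, and this texture places the per-stroke spectral
# arc length of the reference performer near the -1.75 typical of skilled
# discrete movements. The taper keeps the waypoints exact.
b_from_events <- function(event_times, waypoints, n, rate,
                          texture_amp = 0.03, texture_cycles = 3) {
  t <- (seq_len(n) - 1) / rate
  b <- rep(waypoints[1], n)
  for (k in seq_len(length(event_times) - 1)) {
    t0 <- event_times[k]
    t1 <- event_times[k + 1]
    sel <- t >= t0 & t < t1
    tau <- (t[sel] - t0) / (t1 - t0)
    shape <- min_jerk(tau) +
      texture_amp * sin(2 * pi * texture_cycles * tau) * sin(pi * tau)
    b[sel] <- waypoints[k] + (waypoints[k + 1] - waypoints[k]) * shape
  }
  b[t >= event_times[length(event_times)]] <- waypoints[length(waypoints)]
  b[t < event_times[1]] <- waypoints[1]
  b
}

#' Bow-to-arm angle mapping
#'
#' The documented smooth mapping from the bow coordinate to the two
#' driving joints: elbow FE grows quadratically with b (elbow-dominant in
#' the tip half), shoulder AA with the complementary quadratic
#' (shoulder-dominant near the frog), mirroring how string players
#' apportion the bow between the two joints. Both are monotone in b, so
#' scripted bow extents translate into analytic joint ROMs.
#'
#' @param elbow_base,elbow_gain elbow FE at b = 0 and full-range gain
#'   (deg): fe(b) = elbow_base + elbow_gain * b^2.
#' @param shoulder_base,shoulder_gain shoulder AA parameters (deg):
#'   aa(b) = shoulder_base + shoulder_gain * (2b - b^2).
#' @return list of mapping functions and parameters.
#' @export
bow_arm_mapping <- function(elbow_base = 35, elbow_gain = 56.75,
                            shoulder_base = 0, shoulder_gain = 80.1) {
  list(elbow_base = elbow_base, elbow_gain = elbow_gain,
       shoulder_base = shoulder_base, shoulder_gain = shoulder_gain,
       fe = function(b) elbow_base + elbow_gain * b^2,
       aa = function(b) shoulder_base + shoulder_gain * (2 * b - b^2),
       b_from_fe = function(fe) {
         sqrt(pmin(pmax((fe - elbow_base) / elbow_gain, 0), 1))
       })
}

#' Default anthropometry and rig geometry
#'
#' Segment lengths (mm) approximating the study's teacher (181 cm tall)
#' plus the fixed violin/bow geometry of the virtual rig.
#'
#' @param ... named overrides.
#' @return list of geometric constants (mm).
#' @export
default_anthropometry <- function(...) {
  a <- list(upper_arm = 300, forearm = 260, hand = 80,
            elbow_width = 90, wrist_width = 70, hand_width = 60,
            thorax_height = 200, shoulder_up = 120, shoulder_lat = 180,
            bow_length = 740)
  over <- list(...)
  unknown <- setdiff(names(over), names(a))
  if (length(unknown)) {
    stop(sprintf("unknown anthropometry fields: %s",
                 paste(unknown, collapse = ", ")))
  }
  a[names(over)] <- over
  a
}

# rotate vector v about unit axis u by ang degrees (Rodrigues)
rotate_about <- function(v, u, ang) {
  a <- ang * DEG2RAD
  v * cos(a) + pracma_cross(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# secondary (non-driving) angle channels: small smooth oscillations
secondary_angles <- function(t, phase = 0) {
  list(shoulder_e = 75 + 2.5 * sin(2 * pi * 0.23 * t + phase),
       shoulder_ie = -25 + 3 * sin(2 * pi * 0.31 * t + 0.7 + phase),
       elbow_ps = 20 + 4 * sin(2 * pi * 0.27 * t + 1.3 + phase),
       wrist_fe = -8 + 6 * sin(2 * pi * 0.33 * t + 0.4 + phase),
       wrist_aa = 4 + 3 * sin(2 * pi * 0.29 * t + 2.1 + phase))
}

# forward kinematics: joint angles + bow coordinate -> marker series
markers_from_state <- function(angles, b, strings_t, anthro,
                               marker_map = default_marker_map(),
                               noise_sd = 0) {
  n <- length(b)
  rate <- angles$rate
  rt <- array(rep(diag(3), each = n), c(n, 3, 3))  # thorax = lab frame
  t0 <- c(0, 0, 1400)

  # humerus: R_rel = Ry(aa) Rx(e) Ry(ie)
  rh <- array(0, c(n, 3, 3))
  rf <- array(0, c(n, 3, 3))
  rhd <- array(0, c(n, 3, 3))
  for (i in seq_len(n)) {
    rrel <- rot_y(angles$shoulder_aa[i]) %*% rot_x(angles$shoulder_e[i]) %*%
      rot_y(angles$shoulder_ie[i])
    rh[i, , ] <- rrel
    rf[i, , ] <- rrel %*% rot_z(angles$elbow_fe[i]) %*%
      rot_y(angles$elbow_ps[i])
    rhd[i, , ] <- rf[i, , ] %*% rot_z(angles$wrist_fe[i]) %*%
      rot_x(angles$wrist_aa[i])
  }
  shoulder <- matrix(t0, n, 3, byrow = TRUE) +
    cbind(rep(0, n), rep(anthro$shoulder_up, n), rep(anthro$shoulder_lat, n))
  elbow <- shoulder - anthro$upper_arm * rh[, , 2]
  wrist <- elbow - anthro$forearm * rf[, , 2]
  hn3 <- wrist - anthro$hand * rhd[, , 2]

  place <- list(
    C7 = matrix(t0, n, 3, byrow = TRUE) +
      cbind(0, rep(anthro$thorax_height / 2, n), 0),
    T8 = matrix(t0, n, 3, byrow = TRUE) -
      cbind(0, rep(anthro$thorax_height / 2, n), 0),
    IJ = matrix(t0, n, 3, byrow = TRUE) + cbind(rep(60, n), rep(30, n), 0),
    RSHO = shoulder,
    RELL = elbow + anthro$elbow_width / 2 * rh[, , 3],
    RELM = elbow - anthro$elbow_width / 2 * rh[, , 3],
    RWRR = wrist + anthro$wrist_width / 2 * rf[, , 3],
    RWRU = wrist - anthro$wrist_width / 2 * rf[, , 3],
    RHN3 = hn3,
    RHN2 = hn3 + anthro$hand_width * rhd[, , 3])

  # violin fixed in the lab; string line through the bridge midpoint
  p_c <- c(150, 120, 1500)
  u_s <- c(0.9, 0.35, -0.25)
  u_s <- u_s / sqrt(sum(u_s^2))
  lat <- pracma_cross(u_s, c(0, 1, 0))
  lat <- lat / sqrt(sum(lat^2))
  place$VSCR <- matrix(p_c + 260 * u_s, n, 3, byrow = TRUE)
  place$VTAIL <- matrix(p_c - 120 * u_s, n, 3, byrow = TRUE)
  place$VBL <- matrix(p_c + 25 * lat, n, 3, byrow = TRUE)
  place$VBR <- matrix(p_c - 25 * lat, n, 3, byrow = TRUE)

  # bow direction: near-perpendicular to the string, tilted per string
  u_b0 <- pracma_cross(u_s, c(0, 1, 0.2))
  u_b0 <- u_b0 / sqrt(sum(u_b0^2))
  tilt <- ifelse(strings_t == "G", 3, -3)
  # smooth the per-frame tilt so string changes are not instantaneous
  if (length(unique(tilt)) > 1) {
    tilt <- lowpass_vec(tilt, rate, cutoff = 2)
  }
  frog <- matrix(0, n, 3)
  tipm <- matrix(0, n, 3)
  midm <- matrix(0, n, 3)
  L <- anthro$bow_length
  for (i in seq_len(n)) {
    u_b <- rotate_about(u_b0, u_s, tilt[i])
    u_n <- pracma_cross(u_b, u_s)
    u_n <- u_n / sqrt(sum(u_n^2))
    f <- p_c + 2 * u_n - b[i] * L * u_b
    frog[i, ] <- f
    tipm[i, ] <- f + L * u_b
    midm[i, ] <- f + 0.55 * L * u_b + 25 * u_n
  }
  place$BFROG <- frog
  place$BMID <- midm
  place$BTIP <- tipm

  labels <- unname(marker_map[c("c7", "t8", "sternum", "shoulder",
                                "elbow_lat", "elbow_med", "wrist_rad",
                                "wrist_uln", "hand", "hand_rad",
                                "bow_frog", "bow_mid", "bow_tip",
                                "violin_scroll", "violin_bridge_l",
                                "violin_bridge_r", "violin_tail")])
  internal <- c("C7", "T8", "IJ", "RSHO", "RELL", "RELM", "RWRR", "RWRU",
                "RHN3", "RHN2", "BFROG", "BMID", "BTIP", "VSCR", "VBL",
                "VBR", "VTAIL")
  pos <- array(NA_real_, c(n, length(labels), 3))
  for (k in seq_along(internal)) pos[, k, ] <- place[[internal[k]]]
  if (noise_sd > 0) pos <- pos + stats::rnorm(length(pos), 0, noise_sd)
  marker_series(pos, labels, rate)
}

#' Generate the teacher's reference performance
#'
#' The bow coordinate follows the exercise script through per-stroke
#' minimum-jerk profiles; elbow FE and shoulder AA are derived from b by
#' the documented [bow_arm_mapping()]; the remaining channels carry small
#' smooth oscillations; markers are emitted by forward kinematics at the
#' capture rate.
#'
#' @param script an [exercise_script()].
#' @param anthro [default_anthropometry()] values.
#' @param mapping a [bow_arm_mapping()].
#' @param rate capture rate, Hz.
#' @param marker_noise_sd optional additive marker noise (mm).
#' @param seed seed for the marker noise (unused when noise is 0).
#' @return list with `angles` ([joint_angle_series()]), `trace`
#'   (ground-truth bow trace), `markers` ([marker_series()]), `events`
#'   (stroke-boundary times incl. both ends), `script`, `mapping`,
#'   `anthro`.
#' @export
generate_teacher <- function(script, anthro = default_anthropometry(),
                             mapping = bow_arm_mapping(), rate = 120,
                             marker_noise_sd = 0, seed = 1) {
  events <- seq(0, by = script$tempo, length.out = script$n_strokes + 1)
  duration <- events[length(events)]
  n <- round(duration * rate) + 1
  t <- (seq_len(n) - 1) / rate
  b <- b_from_events(events, script$waypoints, n, rate)
  sec <- secondary_angles(t)
  angles <- joint_angle_series(rate,
                               shoulder_aa = mapping$aa(b),
                               shoulder_e = sec$shoulder_e,
                               shoulder_ie = sec$shoulder_ie,
                               elbow_fe = mapping$fe(b),
                               elbow_ps = sec$elbow_ps,
                               wrist_fe = sec$wrist_fe,
                               wrist_aa = sec$wrist_aa)
  strings_t <- script$strings[pmin(pmax(findInterval(t, events,
                                                     rightmost.closed = TRUE),
                                        1), script$n_strokes)]
  if (marker_noise_sd > 0) set.seed(seed)
  markers <- markers_from_state(angles, b, strings_t, anthro,
                                noise_sd = marker_noise_sd)
  list(angles = angles, trace = new_bow_trace(b, rate, anthro$bow_length),
       markers = markers, events = events, script = script,
       mapping = mapping, anthro = anthro)
}

#' Learner deviation profile
#'
#' The knobs of the participant model: how a novice deviates from the
#' teacher's reference.
#'
#' @param amplitude_scale gain on bow excursion about mid-bow (novices
#'   under-use the bow; 1 = full extent).
#' @param lag constant delay behind the teacher, s.
#' @param timing_jitter_sd per-reversal timing jitter SD, s.
#' @param smoothness_noise_sd additive low-frequency bow-coordinate
#'   noise SD, bow-lengths (degrades SPARC and bow fidelity).
#' @param profile_noise_sd per-stroke joint-angle offset SD, deg
#'   (across-stroke variability of elbow FE and shoulder AA).
#' @param coordination_scale multiplier on the elbow-FE gain of the
#'   bow-arm mapping (1 = the teacher's interjoint coordination; the
#'   participant's target elbow-to-shoulder ROM ratio is this multiple
#'   of the teacher's).
#' @param coordination_jitter_sd per-stroke jitter of the elbow-shoulder
#'   coupling angle, deg (drives coordination variability).
#' @param guidance optional [guidance_params()]; non-null switches the
#'   viscous-elastic field on.
#' @return object of class `participant_profile`.
#' @export
participant_profile <- function(amplitude_scale = 1, lag = 0,
                                timing_jitter_sd = 0,
                                smoothness_noise_sd = 0,
                                profile_noise_sd = 0,
                                coordination_scale = 1,
                                coordination_jitter_sd = 0,
                                guidance = NULL) {
  stopifnot(amplitude_scale > 0, timing_jitter_sd >= 0,
            smoothness_noise_sd >= 0, profile_noise_sd >= 0,
            coordination_scale > 0, coordination_jitter_sd >= 0)
  structure(list(amplitude_scale = amplitude_scale, lag = lag,
                 timing_jitter_sd = timing_jitter_sd,
                 smoothness_noise_sd = smoothness_noise_sd,
                 profile_noise_sd = profile_noise_sd,
                 coordination_scale = coordination_scale,
                 coordination_jitter_sd = coordination_jitter_sd,
                 guidance = guidance),
            class = "participant_profile")
}

#' Viscous-elastic guidance parameters
#'
#' The haptic mode applies a restoring action proportional to the error
#' between the measured joint angle and the reference trajectory plus a
#' damping action on the velocity error - a viscous-elastic force field
#' acting at the shoulder (horizontal AA) and elbow (FE).
#'
#' @param stiffness elastic gain toward the reference, 1/s^2 equivalent.
#' @param damping viscous gain on the velocity error, 1/s (default
#'   critical for the given stiffness).
#' @return object of class `guidance_params`.
#' @export
guidance_params <- function(stiffness, damping = 2 * sqrt(stiffness)) {
  stopifnot(stiffness >= 0, damping >= 0)
  structure(list(stiffness = stiffness, damping = damping),
            class = "guidance_params")
}

# damped second-order tracking of a reference trajectory:
#   x'' = theta_p'' + K (theta_ref - x) + C (theta_ref' - x')
# semi-implicit Euler at the capture rate
track_guided <- function(theta_p, theta_ref, stiffness, damping, rate) {
  n <- length(theta_p)
  dt <- 1 / rate
  vp <- c(diff(theta_p), 0) * rate
  vr <- c(diff(theta_ref), 0) * rate
  ap <- c(diff(vp), 0) * rate
  x <- numeric(n)
  x[1] <- theta_p[1]
  v <- vp[1]
  for (i in seq_len(n - 1)) {
    acc <- ap[i] + stiffness * (theta_ref[i] - x[i]) + damping * (vr[i] - v)
    v <- v + acc * dt
    x[i + 1] <- x[i] + v * dt
  }
  x
}

# crossfaded per-stroke offsets: constant within a stroke, linear blend
# of width `blend` seconds across boundaries
stroke_offsets <- function(events, offsets, n, rate, blend = 0.1) {
  t <- (seq_len(n) - 1) / rate
  k <- pmin(pmax(findInterval(t, events, rightmost.closed = TRUE), 1),
            length(offsets))
  out <- offsets[k]
  if (blend > 0 && length(events) > 2) {
    for (j in 2:(length(events) - 1)) {
      sel <- abs(t - events[j]) <= blend / 2
      if (!any(sel)) next
      a <- (t[sel] - (events[j] - blend / 2)) / blend
      out[sel] <- offsets[max(j - 1, 1)] * (1 - a) +
        offsets[min(j, length(offsets))] * a
    }
  }
  out
}

#' Generate a participant performance from the teacher's reference
#'
#' The participant's bow trajectory is the teacher's stroke plan with
#' bow excursion scaled about mid-bow, reversal times shifted by the lag
#' and jittered per stroke, and additive low-frequency noise; joint
#' angles are re-derived through the bow-arm mapping with per-stroke
#' offsets on elbow FE and shoulder AA. When guidance is present, the
#' two guided joints are evolved as damped second-order trackers of the
#' teacher's trajectories (the viscous-elastic field) and the bow
#' coordinate is re-derived from the guided elbow. Markers are emitted
#' by forward kinematics; the analytic ground truth of every scripted
#' deviation is recorded alongside.
#'
#' @param teacher output of [generate_teacher()].
#' @param profile a [participant_profile()].
#' @param seed integer seed for the stochastic deviations.
#' @param marker_noise_sd additive marker noise (mm).
#' @return list with `angles`, `trace`, `markers`, `events`
#'   (ground-truth reversal times), `profile`, `truth` (named list of
#'   analytic expected metric values).
#' @export
generate_participant <- function(teacher, profile, seed = 1,
                                 marker_noise_sd = 0) {
  set.seed(seed)
  script <- teacher$script
  rate <- teacher$angles$rate
  n <- length(teacher$trace$b)
  a <- profile$amplitude_scale
  # participant's own bow-arm mapping: elbow gain scaled by the
  # coordination multiplier
  mapping <- bow_arm_mapping(
    elbow_base = teacher$mapping$elbow_base,
    elbow_gain = teacher$mapping$elbow_gain * profile$coordination_scale,
    shoulder_base = teacher$mapping$shoulder_base,
    shoulder_gain = teacher$mapping$shoulder_gain)

  eta <- stats::rnorm(length(teacher$events), 0, profile$timing_jitter_sd)
  ev <- sort(teacher$events + profile$lag + eta)
  wp <- 0.5 + a * (script$waypoints - 0.5)
  b <- b_from_events(ev, wp, n, rate)
  if (profile$smoothness_noise_sd > 0) {
    noise <- stats::rnorm(n)
    noise <- lowpass_vec(noise, rate, cutoff = 4)
    noise <- noise / stats::sd(noise) * profile$smoothness_noise_sd
    b <- b + noise
  }
  b <- pmin(1, pmax(0, b))

  fe <- mapping$fe(b)
  aa <- mapping$aa(b)
  guided <- FALSE
  if (!is.null(profile$guidance)) {
    g <- profile$guidance
    fe <- track_guided(fe, teacher$angles$elbow_fe, g$stiffness, g$damping,
                       rate)
    aa <- track_guided(aa, teacher$angles$shoulder_aa, g$stiffness,
                       g$damping, rate)
    b <- mapping$b_from_fe(fe)
    guided <- TRUE
  }
  phi <- off_e <- off_s <- rep(0, script$n_strokes)
  if (profile$coordination_jitter_sd > 0) {
    # rotate the per-stroke (elbow, shoulder) path about its centroid:
    # shifts every coupling angle of the stroke by exactly phi_s
    phi <- stats::rnorm(script$n_strokes, 0, profile$coordination_jitter_sd)
    t_all <- (seq_len(n) - 1) / rate
    k_of <- pmin(pmax(findInterval(t_all, ev, rightmost.closed = TRUE), 1),
                 script$n_strokes)
    for (s in seq_len(script$n_strokes)) {
      idx <- which(k_of == s)
      if (length(idx) < 2) next
      ce <- mean(fe[idx]); cs <- mean(aa[idx])
      cphi <- cos(phi[s] * DEG2RAD); sphi <- sin(phi[s] * DEG2RAD)
      de <- fe[idx] - ce; ds <- aa[idx] - cs
      fe[idx] <- ce + cphi * de - sphi * ds
      aa[idx] <- cs + sphi * de + cphi * ds
    }
  }
  if (profile$profile_noise_sd > 0) {
    off_e <- stats::rnorm(script$n_strokes, 0, profile$profile_noise_sd)
    off_s <- stats::rnorm(script$n_strokes, 0, profile$profile_noise_sd)
    fe <- fe + stroke_offsets(ev, off_e, n, rate)
    aa <- aa + stroke_offsets(ev, off_s, n, rate)
  }
  t <- (seq_len(n) - 1) / rate
  sec <- secondary_angles(t, phase = 0.2)
  angles <- joint_angle_series(rate, shoulder_aa = aa,
                               shoulder_e = sec$shoulder_e,
                               shoulder_ie = sec$shoulder_ie,
                               elbow_fe = fe, elbow_ps = sec$elbow_ps,
                               wrist_fe = sec$wrist_fe,
                               wrist_aa = sec$wrist_aa)
  strings_t <- script$strings[pmin(pmax(findInterval(t, teacher$events,
                                                     rightmost.closed = TRUE),
                                        1), script$n_strokes)]
  markers <- markers_from_state(angles, b, strings_t, teacher$anthro,
                                noise_sd = marker_noise_sd)
  truth <- realized_truth(teacher, profile, mapping, ev, eta, wp,
                          phi, off_e, off_s, guided)
  list(angles = angles, trace = new_bow_trace(b, rate, teacher$anthro$bow_length),
       markers = markers, events = ev, profile = profile, guided = guided,
       truth = truth)
}

# ground-truth metric values implied by the scripted deviations and the
# realized random draws (guidance makes most of them non-analytic -> NA)
realized_truth <- function(teacher, profile, mapping, ev, eta, wp,
                           phi, off_e, off_s, guided) {
  script <- teacher$script
  rate <- teacher$angles$rate
  n <- length(teacher$trace$b)
  fe <- mapping$fe
  aa <- mapping$aa
  tm <- stats::setNames(rep(NA_real_, 17), METRIC_IDS)
  if (guided) return(tm)
  bmax <- max(wp)
  bmin <- min(wp)
  tm["m1"] <- bmax - bmin
  tm["m2"] <- fe(bmax) - fe(bmin)
  tm["m3"] <- aa(bmax) - aa(bmin)
  if (bmin < 0.5 && bmax > 0.5) {
    tm["m4"] <- (fe(bmax) - fe(0.5)) / (aa(bmax) - aa(0.5))
    tm["m5"] <- (fe(0.5) - fe(bmin)) / (aa(0.5) - aa(bmin))
    tm["m6"] <- (aa(bmax) - aa(0.5)) / (bmax - 0.5)
    tm["m7"] <- (aa(0.5) - aa(bmin)) / (0.5 - bmin)
    tm["m8"] <- (fe(bmax) - fe(0.5)) / (bmax - 0.5)
    tm["m9"] <- (fe(0.5) - fe(bmin)) / (0.5 - bmin)
  }
  # stroke classes as the segmentation will see them
  grp <- paste(script$directions,
               classify_extent(pmin(wp[-length(wp)], wp[-1]),
                               pmax(wp[-length(wp)], wp[-1])))
  grouped_sd <- function(x, circular = FALSE) {
    vals <- c(); wts <- c()
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (length(rows) < 2) next
      vals <- c(vals, if (circular) circ_sd_deg(x[rows] * DEG2RAD)
                else stats::sd(x[rows]))
      wts <- c(wts, length(rows))
    }
    if (length(vals) == 0) return(NA_real_)
    stats::weighted.mean(vals, wts)
  }
  tm["m10"] <- grouped_sd(off_e)
  tm["m11"] <- grouped_sd(off_s)
  tm["m12"] <- grouped_sd(phi, circular = TRUE)
  interior <- seq(2, length(teacher$events) - 1)
  tm["m13"] <- sum((ev - teacher$events)[interior])
  b_det <- b_from_events(ev, wp, n, rate)
  tm["m14"] <- 100 * sqrt(mean((b_det - teacher$trace$b)^2) +
                            profile$smoothness_noise_sd^2)
  # realized phases of the participant reversals within teacher cycles
  tev <- teacher$events[interior]
  pev <- ev[interior]
  phases <- wrap_pi(2 * pi * (pev - tev) / script$tempo)
  res <- circ_resultant(phases)
  tm["m16"] <- res$rbar
  tm["m17"] <- wrap_pi(res$mean)
  tm
}
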