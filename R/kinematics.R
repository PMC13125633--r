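# Segment coordinate frames, ISB-convention joint angles and the
# normalized bow-string contact coordinate.
#
# Segment frames follow the ISB recommendation in spirit: Y along the
# segment long axis pointing proximally, X anterior, Z lateral, built from
# three markers per segment. The shoulder uses the mobile Y-X'-Y'' sequence
# (plane of elevation / horizontal abduction-adduction, elevation, axial
# rotation); elbow and wrist use Z-X-Y (flexion-extension first, axial
# rotation last).

#' Default anatomical role to marker label map
#'
#' Roles cover the right bowing arm, the trunk, the violin and the bow.
#' Override any entry to adapt to a different marker set, e.g.
#' `default_marker_map(shoulder = "R_SHOULDER")`.
#'
#' @param ... named role overrides (role = label).
#' @return named character vector mapping roles to marker labels.
#' @export
default_marker_map <- function(...) {
  map <- c(c7 = "C7", t8 = "T8", sternum = "IJ",
           shoulder = "RSHO", elbow_lat = "RELL", elbow_med = "RELM",
           wrist_rad = "RWRR", wrist_uln = "RWRU",
           hand = "RHN3", hand_rad = "RHN2",
           bow_frog = "BFROG", bow_mid = "BMID", bow_tip = "BTIP",
           violin_scroll = "VSCR", violin_bridge_l = "VBL",
           violin_bridge_r = "VBR", violin_tail = "VTAIL")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(map))
    if (length(unknown)) {
      stop(sprintf("unknown marker roles: %s", paste(unknown, collapse = ", ")))
    }
    map[names(over)] <- over
  }
  map
}

role_xyz <- function(series, marker_map, role) {
  lab <- marker_map[[role]]
  if (is.null(lab) || is.na(lab)) {
    stop(sprintf("marker map is missing required role '%s'", role))
  }
  if (!lab %in% series$labels) {
    stop(sprintf("marker '%s' (role '%s') not present in series", lab, role))
  }
  marker_xyz(series, lab)
}

#' Build per-frame segment coordinate frames from markers
#'
#' Constructs thorax, humerus, forearm and hand frames (plus bow and
#' violin marker bundles) from a cleaned marker series. Constructions:
#' \describe{
#'   \item{thorax}{Y = C7 - T8 (up), anterior reference = sternum - T8.}
#'   \item{humerus}{Y = shoulder - elbow midpoint, lateral reference =
#'     lateral - medial elbow marker.}
#'   \item{forearm}{Y = elbow midpoint - wrist midpoint, lateral
#'     reference = radial - ulnar wrist marker.}
#'   \item{hand}{Y = wrist midpoint - hand marker, lateral reference =
#'     radial hand marker - hand marker.}
#' }
#' Every frame is orthonormal with determinant +1; collinear marker
#' triples raise a degenerate-geometry error naming the offending frame.
#'
#' @param series a [marker_series()] with all occlusions filled.
#' @param marker_map named role->label map, see [default_marker_map()].
#' @return list with per-segment `list(origin, r)` entries (`origin`
#'   `n x 3` mm, `r` rotation stack `c(n, 3, 3)`).
#' @export
build_frames <- function(series, marker_map = default_marker_map()) {
  if (any(series$occluded)) {
    stop("series contains occluded entries; fill or trim before build_frames()")
  }
  g <- function(role) role_xyz(series, marker_map, role)
  c7 <- g("c7"); t8 <- g("t8"); ij <- g("sternum")
  sho <- g("shoulder"); ell <- g("elbow_lat"); elm <- g("elbow_med")
  wrr <- g("wrist_rad"); wru <- g("wrist_uln")
  hn3 <- g("hand"); hn2 <- g("hand_rad")

  elb <- (ell + elm) / 2
  wri <- (wrr + wru) / 2

  thorax <- frames_from_axes(c7 - t8, ij - t8, ref_axis = "x", what = "thorax")
  humerus <- frames_from_axes(sho - elb, ell - elm, ref_axis = "z",
                              what = "humerus")
  forearm <- frames_from_axes(elb - wri, wrr - wru, ref_axis = "z",
                              what = "forearm")
  hand <- frames_from_axes(wri - hn3, hn2 - hn3, ref_axis = "z", what = "hand")

  list(thorax = list(origin = (c7 + t8) / 2, r = thorax),
       humerus = list(origin = sho, r = humerus),
       forearm = list(origin = elb, r = forearm),
       hand = list(origin = wri, r = hand))
}

#' Joint-angle series container
#'
#' Seven per-frame anatomical angle channels in degrees, all unwrapped
#' (no +-180 degree jumps between adjacent frames).
#'
#' @param rate sampling rate (Hz).
#' @param shoulder_aa,shoulder_e,shoulder_ie shoulder horizontal
#'   abduction-adduction (plane of elevation), elevation, internal(+)-
#'   external rotation.
#' @param elbow_fe,elbow_ps elbow flexion-extension (0 = full extension)
#'   and pronation(+)-supination.
#' @param wrist_fe,wrist_aa wrist flexion(+)-extension and radial(+)-
#'   ulnar deviation.
#' @return object of class `joint_angle_series` (a list of equal-length
#'   numeric vectors plus `rate`).
#' @export
joint_angle_series <- function(rate, shoulder_aa, shoulder_e, shoulder_ie,
                               elbow_fe, elbow_ps, wrist_fe, wrist_aa) {
  ch <- list(shoulder_aa = shoulder_aa, shoulder_e = shoulder_e,
             shoulder_ie = shoulder_ie, elbow_fe = elbow_fe,
             elbow_ps = elbow_ps, wrist_fe = wrist_fe, wrist_aa = wrist_aa)
  n <- unique(vapply(ch, length, 1L))
  if (length(n) != 1) stop("all angle channels must have equal length")
  structure(c(list(rate = rate), ch), class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d frames @ %g Hz\n",
              length(x$elbow_fe), x$rate))
  invisible(x)
}

#' Shoulder angles from thorax and humerus frames
#'
#' Y-X'-Y'' decomposition of the humerus orientation relative to the
#' thorax: `aa` = plane of elevation (horizontal abduction-adduction,
#' adduction positive), `e` = elevation (positive upward, in [0, 180]),
#' `ie` = axial rotation (internal positive). Channels are unwrapped for
#' continuity; gimbal-adjacent frames carry the previous frame's `aa`.
#'
#' @param thorax,humerus rotation stacks `c(n, 3, 3)` from [build_frames()].
#' @return list with numeric vectors `aa`, `e`, `ie` (deg) and logical
#'   `gimbal`.
#' @export
shoulder_angles <- function(thorax, humerus) {
  e <- euler_yxy(relative_rotation(thorax, humerus))
  list(aa = unwrap_deg(unname(e[, "a"])), e = unname(e[, "b"]),
       ie = unwrap_deg(unname(e[, "c"])), gimbal = attr(e, "gimbal"))
}

#' Elbow angles from humerus and forearm frames
#'
#' Z-X-Y decomposition of the forearm orientation relative to the
#' humerus: `fe` = flexion-extension (0 at full extension, flexion
#' positive), `ps` = pronation(+)-supination.
#'
#' @param humerus,forearm rotation stacks `c(n, 3, 3)`.
#' @return list with numeric vectors `fe`, `ps` (deg).
#' @export
elbow_angles <- function(humerus, forearm) {
  e <- euler_zxy(relative_rotation(humerus, forearm))
  list(fe = unwrap_deg(unname(e[, "a"])), ps = unwrap_deg(unname(e[, "c"])))
}

#' Wrist angles from forearm and hand frames
#'
#' Z-X-Y decomposition of the hand orientation relative to the forearm:
#' `fe` = flexion(+)-extension, `aa` = radial(+)-ulnar deviation.
#'
#' @param forearm,hand rotation stacks `c(n, 3, 3)`.
#' @return list with numeric vectors `fe`, `aa` (deg).
#' @export
wrist_angles <- function(forearm, hand) {
  e <- euler_zxy(relative_rotation(forearm, hand))
  list(fe = unwrap_deg(unname(e[, "a"])), aa = unwrap_deg(unname(e[, "b"])))
}

#' Compute all joint angles from a marker series
#'
#' Convenience wrapper: [build_frames()] then the three angle
#' decompositions, returned as a [joint_angle_series()].
#'
#' @inheritParams build_frames
#' @return a [joint_angle_series()].
#' @export
joint_angles <- function(series, marker_map = default_marker_map()) {
  fr <- build_frames(series, marker_map)
  sh <- shoulder_angles(fr$thorax$r, fr$humerus$r)
  el <- elbow_angles(fr$humerus$r, fr$forearm$r)
  wr <- wrist_angles(fr$forearm$r, fr$hand$r)
  joint_angle_series(series$rate, sh$aa, sh$e, sh$ie, el$fe, el$ps,
                     wr$fe, wr$aa)
}

#' Normalized bow-string contact coordinate
#'
#' Per frame, the bow long axis is the frog-to-tip line and the string
#' line runs along the violin long axis (scroll minus tailpiece) through
#' the bridge midpoint. The contact coordinate `b` is the parameter of
#' the point of closest approach between the two lines along the bow
#' axis, divided by the bow length: 0 at the frog, 1 at the tip, clipped
#' to [0, 1]. `v` is the centered finite difference of `b` times the
#' rate (one-sided at the ends). Frames where the lines are within 1
#' degree of parallel carry the previous frame's `b` and are flagged.
#'
#' @param series a [marker_series()] containing bow and violin markers.
#' @param marker_map role->label map, see [default_marker_map()].
#' @return object of class `bow_trace`: list with `rate`, `b`, `v`,
#'   `bow_length` (mm), `clip_rate`, `parallel` (logical flags).
#' @export
bow_trace <- function(series, marker_map = default_marker_map()) {
  frog <- role_xyz(series, marker_map, "bow_frog")
  tip <- role_xyz(series, marker_map, "bow_tip")
  scroll <- role_xyz(series, marker_map, "violin_scroll")
  tail <- role_xyz(series, marker_map, "violin_tail")
  bl <- role_xyz(series, marker_map, "violin_bridge_l")
  br <- role_xyz(series, marker_map, "violin_bridge_r")

  d1 <- tip - frog
  d2 <- scroll - tail
  p2 <- (bl + br) / 2
  w <- frog - p2
  a <- rowSums(d1 * d1)
  bb <- rowSums(d1 * d2)
  cc <- rowSums(d2 * d2)
  dd <- rowSums(d1 * w)
  ee <- rowSums(d2 * w)
  denom <- a * cc - bb * bb
  sin2 <- denom / (a * cc)  # sin^2 of the angle between the lines
  parallel <- sin2 < sin(1 * DEG2RAD)^2
  s <- (bb * ee - cc * dd) / denom
  if (any(parallel)) {
    idx <- which(parallel)
    for (i in idx) s[i] <- if (i > 1) s[i - 1] else 0.5
  }
  n_over <- sum(s < 0 | s > 1)
  b <- pmin(1, pmax(0, s))
  new_bow_trace(b, series$rate, bow_length = mean(sqrt(a)),
                clip_rate = n_over / length(b), parallel = parallel)
}

# construct a bow_trace from a raw b series (also used by the simulator)
new_bow_trace <- function(b, rate, bow_length = 740, clip_rate = 0,
                          parallel = NULL) {
  n <- length(b)
  v <- numeric(n)
  if (n >= 3) v[2:(n - 1)] <- (b[3:n] - b[1:(n - 2)]) / 2 * rate
  if (n >= 2) {
    v[1] <- (b[2] - b[1]) * rate
    v[n] <- (b[n] - b[n - 1]) * rate
  }
  structure(list(rate = rate, b = b, v = v, bow_length = bow_length,
                 clip_rate = clip_rate,
                 parallel = parallel %||% rep(FALSE, n)),
            class = "bow_trace")
}

#' @export
print.bow_trace <- function(x, ...) {
  cat(sprintf("<bow_trace> %d frames @ %g Hz, bow %.0f mm, b in [%.3f, %.3f], clipped %.2f%%\n",
              length(x$b), x$rate, x$bow_length, min(x$b), max(x$b),
              100 * x$clip_rate))
  invisible(x)
}

#' Export joint angles as a tidy table
#'
#' @param angles a [joint_angle_series()].
#' @return data.frame with columns `frame`, `time_s`, `channel`,
#'   `value_deg` (long format).
#' @export
angles_to_table <- function(angles) {
  chans <- c("shoulder_aa", "shoulder_e", "shoulder_ie", "elbow_fe",
             "elbow_ps", "wrist_fe", "wrist_aa")
  n <- length(angles$elbow_fe)
  do.call(rbind, lapply(chans, function(ch) {
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / angles$rate,
               channel = ch, value_deg = angles[[ch]])
  }))
}
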