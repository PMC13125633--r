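# Segment frames, Euler decompositions, bow-string geometry and the
# marker -> angle round trip.

rot_x <- bowkin:::rot_x
rot_y <- bowkin:::rot_y
rot_z <- bowkin:::rot_z

test_that("Euler decompositions recompose to the original rotation", {
  set.seed(11)
  for (i in 1:25) {
    a <- runif(1, -170, 170)
    b_yxy <- runif(1, 5, 175)     # away from the YXY gimbal
    b_zxy <- runif(1, -80, 80)    # away from the ZXY gimbal
    cc <- runif(1, -170, 170)
    r1 <- rot_y(a) %*% rot_x(b_yxy) %*% rot_y(cc)
    stack <- array(r1, c(1, 3, 3))
    stack[1, , ] <- r1
    e <- bowkin:::euler_yxy(stack)
    r1b <- rot_y(e[1, "a"]) %*% rot_x(e[1, "b"]) %*% rot_y(e[1, "c"])
    expect_lt(max(abs(r1 - r1b)), 1e-9)
    r2 <- rot_z(a) %*% rot_x(b_zxy) %*% rot_y(cc)
    stack[1, , ] <- r2
    e2 <- bowkin:::euler_zxy(stack)
    r2b <- rot_z(e2[1, "a"]) %*% rot_x(e2[1, "b"]) %*% rot_y(e2[1, "c"])
    expect_lt(max(abs(r2 - r2b)), 1e-9)
  }
})

test_that("single-axis shoulder and elbow cases give the axis angle", {
  id <- array(diag(3), c(1, 3, 3))
  r30 <- array(rot_y(30), c(1, 3, 3))
  sh <- shoulder_angles(id, r30)
  # pure rotation about the thorax vertical axis: axial/plane split is
  # degenerate at zero elevation; the total about Y must be 30
  expect_equal(sh$e[1], 0, tolerance = 1e-6)
  expect_equal(sh$aa[1] + sh$ie[1], 30, tolerance = 1e-6)
  sh0 <- shoulder_angles(id, id)
  expect_equal(c(sh0$aa, sh0$e, sh0$ie), c(0, 0, 0), tolerance = 1e-9)
  el <- elbow_angles(id, array(rot_z(90), c(1, 3, 3)))
  expect_equal(el$fe[1], 90, tolerance = 1e-9)
  el0 <- elbow_angles(id, id)
  expect_equal(c(el0$fe, el0$ps), c(0, 0), tolerance = 1e-12)
  wr <- wrist_angles(id, array(rot_z(20), c(1, 3, 3)))
  expect_equal(c(wr$fe[1], wr$aa[1]), c(20, 0), tolerance = 1e-9)
})

test_that("elbow flexion matches a vector-geometry oracle", {
  set.seed(12)
  for (i in 1:10) {
    hum <- array(rot_y(runif(1, -90, 90)) %*% rot_x(runif(1, 10, 170)),
                 c(1, 3, 3))
    fe_true <- runif(1, 5, 170)
    fore <- array(hum[1, , ] %*% rot_z(fe_true), c(1, 3, 3))
    el <- elbow_angles(hum, fore)
    expect_equal(el$fe[1], fe_true, tolerance = 1e-9)
    # oracle: angle between the segments' long axes
    ang <- acos(sum(hum[1, , 2] * fore[1, , 2])) * 180 / pi
    expect_equal(el$fe[1], ang, tolerance = 1e-9)
  }
})

test_that("build_frames reproduces canonical and rotated placements", {
  te <- generate_teacher(exercise_script(1))
  fr <- build_frames(te$markers)
  # thorax is lab-aligned in the rig: identity orientation
  expect_lt(max(abs(fr$thorax$r[1, , ] - diag(3))), 1e-9)
  for (seg in fr) {
    r <- seg$r[10, , ]
    expect_lt(max(abs(t(r) %*% r - diag(3))), 1e-9)
    expect_equal(det(r), 1, tolerance = 1e-9)
  }
  # a global rigid transform rotates every frame by the same rotation
  rot <- rot_z(35) %*% rot_x(10)
  m2 <- te$markers
  n <- n_frames(m2)
  for (k in seq_along(m2$labels)) {
    m2$positions[, k, ] <- m2$positions[, k, ] %*% t(rot) +
      matrix(c(100, -50, 30), n, 3, byrow = TRUE)
  }
  fr2 <- build_frames(m2)
  for (nm in names(fr)) {
    expect_lt(max(abs(fr2[[nm]]$r[5, , ] - rot %*% fr[[nm]]$r[5, , ])), 1e-9)
  }
  # and leaves all joint angles unchanged
  ja <- joint_angles(te$markers)
  ja2 <- joint_angles(m2)
  for (ch in c("shoulder_aa", "shoulder_e", "elbow_fe", "wrist_fe")) {
    expect_lt(max(abs(ja[[ch]] - ja2[[ch]])), 1e-8)
  }
})

test_that("collinear markers raise a degenerate-geometry error", {
  te <- generate_teacher(exercise_script(1))
  m <- te$markers
  i_ij <- match("IJ", m$labels)
  i_c7 <- match("C7", m$labels)
  m$positions[, i_ij, ] <- m$positions[, i_c7, ]  # sternum onto C7 line
  expect_error(build_frames(m), "thorax")
})

test_that("missing marker-map roles are reported by name", {
  te <- generate_teacher(exercise_script(1))
  mm <- default_marker_map(shoulder = "NOPE")
  expect_error(build_frames(te$markers, mm), "NOPE")
  expect_error(default_marker_map(no_such_role = "X"), "unknown")
})

test_that("bow coordinate matches closest-approach geometry", {
  # frog at origin, tip at (740,0,0), string crossing at x = 370
  n <- 2
  pos <- array(0, c(n, 7, 3))
  labs <- c("BFROG", "BMID", "BTIP", "VSCR", "VBL", "VBR", "VTAIL")
  for (i in 1:n) {
    pos[i, 1, ] <- c(0, 0, 0)
    pos[i, 2, ] <- c(407, 30, 0)
    pos[i, 3, ] <- c(740, 0, 0)
    pos[i, 4, ] <- c(370, 0, 300)     # scroll
    pos[i, 5, ] <- c(360, 10, 50)     # bridge left
    pos[i, 6, ] <- c(380, 10, 50)     # bridge right
    pos[i, 7, ] <- c(370, 0, -100)    # tailpiece
  }
  s <- marker_series(pos, labs, 120)
  bt <- bow_trace(s)
  expect_equal(bt$b[1], 0.5, tolerance = 1e-9)
  pos2 <- pos
  pos2[, 4:7, 1] <- pos2[, 4:7, 1] - 370   # string crossing at the frog
  bt2 <- bow_trace(marker_series(pos2, labs, 120))
  expect_equal(bt2$b[1], 0, tolerance = 1e-9)
})

test_that("closest-approach parameter matches a dense-sampling oracle", {
  set.seed(13)
  for (i in 1:8) {
    frog <- rnorm(3, 0, 100)
    u_b <- rnorm(3); u_b <- u_b / sqrt(sum(u_b^2))
    p2 <- rnorm(3, 0, 100)
    u_s <- rnorm(3); u_s <- u_s / sqrt(sum(u_s^2))
    if (abs(sum(u_b * u_s)) > 0.95) next
    L <- 740
    pos <- array(0, c(1, 7, 3))
    pos[1, 1, ] <- frog
    pos[1, 2, ] <- frog + 0.55 * L * u_b + c(10, 10, 0)
    pos[1, 3, ] <- frog + L * u_b
    pos[1, 4, ] <- p2 + 260 * u_s
    lat <- c(u_s[2], -u_s[1], 0); lat <- lat / sqrt(sum(lat^2))
    pos[1, 5, ] <- p2 + 25 * lat
    pos[1, 6, ] <- p2 - 25 * lat
    pos[1, 7, ] <- p2 - 120 * u_s
    s <- marker_series(pos, c("BFROG", "BMID", "BTIP", "VSCR", "VBL",
                              "VBR", "VTAIL"), 120)
    bt <- bow_trace(s)
    # oracle: densely sample the bow axis, minimize distance to the line
    ss <- seq(0, 1, length.out = 1e5)
    pts <- outer(ss * L, u_b) + matrix(frog, length(ss), 3, byrow = TRUE)
    w <- pts - matrix(p2, length(ss), 3, byrow = TRUE)
    along <- w %*% u_s
    d2 <- rowSums(w^2) - along^2
    b_oracle <- min(max(ss[which.min(d2)], 0), 1)
    expect_lt(abs(bt$b[1] - b_oracle), 1e-3)
  }
})

test_that("bow coordinate is invariant to a rigid lab-frame change", {
  te <- generate_teacher(exercise_script(1))
  bt <- bow_trace(te$markers)
  rot <- rot_y(50) %*% rot_z(-20)
  m2 <- te$markers
  for (k in seq_along(m2$labels)) {
    m2$positions[, k, ] <- m2$positions[, k, ] %*% t(rot) + 500
  }
  bt2 <- bow_trace(m2)
  expect_lt(max(abs(bt$b - bt2$b)), 1e-9)
})

test_that("markers from known angles round-trip noise-free to 1e-6 deg", {
  for (e in c(1, 2)) {
    te <- generate_teacher(exercise_script(e))
    ja <- joint_angles(te$markers)
    for (ch in c("shoulder_aa", "shoulder_e", "shoulder_ie", "elbow_fe",
                 "elbow_ps", "wrist_fe", "wrist_aa")) {
      expect_lt(max(abs(ja[[ch]] - te$angles[[ch]])), 1e-6)
    }
    bt <- bow_trace(te$markers)
    expect_lt(max(abs(bt$b - te$trace$b)), 1e-6)
  }
})

test_that("angles recover within 0.5 deg RMS under 1 mm marker noise", {
  te <- generate_teacher(exercise_script(1), marker_noise_sd = 1, seed = 7)
  ja <- joint_angles(lowpass(te$markers, 10))
  for (ch in c("shoulder_aa", "shoulder_e", "shoulder_ie", "elbow_fe",
               "elbow_ps", "wrist_fe", "wrist_aa")) {
    expect_lt(rms(ja[[ch]] - te$angles[[ch]]), 0.5)
  }
})
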