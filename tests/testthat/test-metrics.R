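# The 17 performance metrics against independent oracles.

test_that("rom handles sinusoids, constants, masks and degenerate input", {
  t <- seq(0, 2, by = 1 / 120)
  x <- 20 * sin(2 * pi * t)
  expect_equal(rom(x), 40, tolerance = 1e-3)
  expect_equal(rom(rep(5, 10)), 0)
  set.seed(31)
  ch <- rnorm(200)
  mask <- runif(200) > 0.5
  expect_equal(rom(ch, mask), max(ch[mask]) - min(ch[mask]))
  expect_true(is.na(rom(ch, rep(FALSE, 200))))
  # invariance to offset, linearity in gain
  expect_equal(rom(ch + 100), rom(ch))
  expect_equal(rom(3 * ch), 3 * rom(ch))
})

test_that("spatial block ratios follow proportional signals", {
  t <- seq(0, 4, by = 1 / 120)
  b <- 0.5 + 0.4 * sin(2 * pi * 0.5 * t)
  tr <- make_trace(b)
  aa <- 30 + 10 * sin(2 * pi * 0.5 * t)
  fe <- 2 * aa
  ja <- joint_angle_series(120, shoulder_aa = aa, shoulder_e = aa * 0,
                           shoulder_ie = aa * 0, elbow_fe = fe,
                           elbow_ps = aa * 0, wrist_fe = aa * 0,
                           wrist_aa = aa * 0)
  sb <- spatial_block(ja, tr)
  expect_equal(unname(sb["m4"]), 2, tolerance = 1e-6)
  expect_equal(unname(sb["m5"]), 2, tolerance = 1e-6)
  expect_equal(unname(sb["m1"]), 0.8, tolerance = 1e-3)
})

test_that("ratios over an empty bow half are undefined markers", {
  tr <- make_trace(seq(0.05, 0.45, length.out = 120))  # never enters tip half
  z <- numeric(120)
  ja <- joint_angle_series(120, z + 1, z, z, z + 2, z, z, z)
  sb <- spatial_block(ja, tr)
  expect_true(all(is.na(sb[c("m4", "m6", "m8")])))
  expect_false(is.na(sb["m1"]))
})

test_that("variability matches two-point and Monte-Carlo references", {
  base <- sin(seq(0, pi, length.out = 101))
  expect_equal(variability(rbind(base, base)), 0)
  expect_equal(variability(rbind(base, base + 2)), sqrt(2), tolerance = 1e-9)
  set.seed(32)
  offs <- rnorm(300, 0, 3)
  pr <- t(vapply(offs, function(o) base + o, numeric(101)))
  expect_equal(variability(pr), sd(offs), tolerance = 1e-6)
  expect_equal(variability(pr), 3, tolerance = 0.3)
  expect_true(is.na(variability(rbind(base))))
})

test_that("coordination variability agrees with circular statistics", {
  base_e <- cumsum(rep(1, 101))
  base_s <- cumsum(rep(0.5, 101))
  expect_equal(coordination_variability(rbind(base_e, base_e),
                                        rbind(base_s, base_s)), 0,
               tolerance = 1e-4)
  # four strokes whose coupling angles sit at 0, 90, 180, 270 degrees:
  # fully dispersed -> the documented cap applies at every step
  pe <- rbind(cumsum(rep(1, 101)), cumsum(rep(0, 101)) ,
              cumsum(rep(-1, 101)), cumsum(rep(0, 101)))
  ps_ <- rbind(cumsum(rep(0, 101)), cumsum(rep(1, 101)),
               cumsum(rep(0, 101)), cumsum(rep(-1, 101)))
  got <- coordination_variability(pe, ps_, trim = 0, min_motion = 0)
  cap <- sqrt(-2 * log(bowkin:::CIRC_RBAR_MIN)) * 180 / pi
  expect_equal(got, cap, tolerance = 1e-6)
  # small angular jitter: metric converges to the jitter SD
  set.seed(33)
  for (sigma in c(2, 5)) {
    phis <- rnorm(200, 0, sigma) * pi / 180
    pe2 <- t(vapply(phis, function(p) cumsum(rep(cos(p), 101)), numeric(101)))
    ps2 <- t(vapply(phis, function(p) cumsum(rep(sin(p), 101)), numeric(101)))
    got <- coordination_variability(pe2, ps2)
    expect_equal(got, sigma, tolerance = 0.15 * sigma)
  }
})

test_that("timing difference sums signed offsets over matched events", {
  ev <- seq(1, 10)
  expect_equal(as.numeric(timing_difference(ev, ev)), 0)
  expect_equal(as.numeric(timing_difference(ev + 0.5, ev)), 5.0)
  expect_equal(as.numeric(timing_difference(ev - 0.3, ev)), -3.0,
               tolerance = 1e-9)
  expect_true(is.na(timing_difference(numeric(), ev)))
})

test_that("greedy matching equals exhaustive assignment on small trains", {
  # oracle: optimal one-to-one assignment by total |dt| over permutations
  exhaustive <- function(p, t) {
    perms <- pracma::perms(seq_along(p))
    best <- Inf; best_sum <- NA
    for (r in seq_len(nrow(perms))) {
      cost <- sum(abs(p[perms[r, ]] - t))
      if (cost < best) {
        best <- cost
        best_sum <- sum(p[perms[r, ]] - t)
      }
    }
    best_sum
  }
  set.seed(34)
  for (i in 1:10) {
    t_ev <- cumsum(runif(6, 1.2, 1.8))
    p_ev <- t_ev + rnorm(6, 0.1, 0.15)
    expect_equal(as.numeric(timing_difference(p_ev, t_ev)),
                 exhaustive(p_ev, t_ev), tolerance = 1e-9)
  }
})

test_that("bow distance is an RMS in percent of bow length", {
  b <- runif(200)
  tr <- make_trace(b)
  expect_equal(euclidean_distance(tr, tr), 0)
  tr2 <- make_trace(b * 0 + 0.25)
  tr3 <- make_trace(b * 0 + 0.50)
  expect_equal(euclidean_distance(tr2, tr3), 25)
  set.seed(35)
  x <- make_trace(runif(300)); y <- make_trace(runif(300))
  expect_equal(euclidean_distance(x, y),
               100 * sqrt(sum((x$b - y$b)^2) / 300), tolerance = 1e-9)
  # symmetry
  expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))
  expect_error(euclidean_distance(x, make_trace(runif(10))), "aligned")
})

test_that("SPARC matches an independent spectral transcription", {
  # oracle: direct O(N^2) DFT evaluation of the published definition
  sparc_oracle <- function(v, rate, f_max = 10, thr = 0.05, pad = 4) {
    nfft <- 2^ceiling(log2(length(v) * pad))
    vv <- c(v, rep(0, nfft - length(v)))
    k <- 0:(nfft / 2)
    mag <- vapply(k, function(ki) {
      Mod(sum(vv * exp(-2i * pi * ki * (seq_along(vv) - 1) / nfft)))
    }, 0)
    f <- k * rate / nfft
    magn <- mag / mag[1]
    icut <- max(which(f <= f_max & magn >= thr), 2)
    sel <- 1:icut
    -sum(sqrt((diff(f[sel]) / f[icut])^2 + diff(magn[sel])^2))
  }
  t <- seq(0, 1.5, by = 1 / 120)
  bump <- exp(-(t - 0.75)^2 / (2 * 0.15^2))
  expect_equal(sparc(bump, 120), sparc_oracle(bump, 120), tolerance = 1e-6)
  two <- bump + 0.8 * exp(-(t - 0.35)^2 / (2 * 0.05^2))
  expect_equal(sparc(two, 120), sparc_oracle(two, 120), tolerance = 1e-6)
  # amplitude-scale invariance
  expect_equal(sparc(2 * bump, 120), sparc(bump, 120), tolerance = 1e-12)
  # time-shift invariance (magnitude spectrum)
  shifted <- exp(-(t - 0.55)^2 / (2 * 0.15^2))
  expect_equal(sparc(shifted, 120), sparc(bump, 120), tolerance = 1e-3)
  # superimposed submovements are strictly less smooth
  expect_lt(sparc(two, 120), sparc(bump, 120))
})

test_that("synchronization strength and phase follow circular statistics", {
  tev <- seq(0, 10)
  sy <- synchronization(tev, tev)
  expect_equal(sy$strength, 1)
  expect_equal(sy$phase, 0)
  # balanced phases cancel
  tev4 <- c(0, 1, 2, 3, 4)
  pev <- c(0, 1.25, 2.5, 2.75)   # phases 0, pi/2, pi, -pi/2
  sy2 <- synchronization(pev, tev4)
  expect_equal(sy2$strength, 0, tolerance = 1e-9)
  # von Mises phases: strength estimates A(kappa) = I1(kappa)/I0(kappa)
  kappa <- 5
  set.seed(36)
  n <- 200
  # sample von Mises by rejection (Best-Fisher)
  rvm <- function(n, kappa) {
    out <- numeric(0)
    while (length(out) < n) {
      th <- runif(n, -pi, pi)
      keep <- runif(n) < exp(kappa * (cos(th) - 1))
      out <- c(out, th[keep])
    }
    out[1:n]
  }
  phases <- rvm(n, kappa)
  tev2 <- seq(0, n)
  pev2 <- tev2[1:n] + phases / (2 * pi)
  sy3 <- synchronization(pev2, tev2)
  a_kappa <- besselI(kappa, 1) / besselI(kappa, 0)
  expect_equal(sy3$strength, a_kappa, tolerance = 0.05)
  # fewer than 2 teacher intervals: undefined markers
  expect_true(is.na(synchronization(c(1, 2), c(1, 2))$strength))
})

test_that("synchronization is invariant to a common time shift", {
  set.seed(37)
  tev <- cumsum(runif(10, 1.2, 1.8))
  pev <- tev + rnorm(10, 0.1, 0.08)
  a <- synchronization(pev, tev)
  b <- synchronization(pev + 13.7, tev + 13.7)
  expect_equal(a$strength, b$strength, tolerance = 1e-12)
  expect_equal(a$phase, b$phase, tolerance = 1e-12)
})

test_that("compute_all propagates undefined markers on degraded input", {
  te <- generate_teacher(exercise_script(1))
  kin <- list(angles = te$angles, trace = te$trace)
  # teacher against itself: perfect spatiotemporal agreement
  mv <- compute_all(kin, kin, trial_meta(1, "AV", 1, "S1"))
  expect_equal(unname(mv["m13"]), 0)
  expect_equal(unname(mv["m14"]), 0)
  expect_equal(unname(mv["m16"]), 1)
  expect_equal(unname(mv["m17"]), 0)
  # flat trace: no strokes -> stroke-based metrics undefined, spatial kept
  n <- length(te$trace$b)
  flat <- list(angles = te$angles, trace = make_trace(rep(0.4, n)))
  mv2 <- compute_all(flat, kin, trial_meta(1, "AV", 1, "S1"))
  expect_true(all(is.na(mv2[c("m10", "m11", "m12", "m13", "m16", "m17")])))
  expect_false(anyNA(mv2[c("m1", "m2", "m3")]))
})

test_that("m14 grows with the deviation scale of the participant model", {
  te <- generate_teacher(exercise_script(1))
  kin <- list(angles = te$angles, trace = te$trace)
  med14 <- vapply(c(0.005, 0.02, 0.05), function(s) {
    vals <- vapply(1:4, function(r) {
      pa <- generate_participant(te, participant_profile(
        smoothness_noise_sd = s), seed = 40 + r)
      unname(compute_all(list(angles = pa$angles, trace = pa$trace), kin,
                         trial_meta(2, "AV", 1, "S1"))["m14"])
    }, 0)
    median(vals)
  }, 0)
  expect_true(all(diff(med14) > 0))
})
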