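# shared fixture builders (all data generated in code)

# small random marker series with optional occlusions
make_series <- function(n = 10, m = 3, rate = 120, seed = 1,
                        occlude = NULL, start_time = 0) {
  set.seed(seed)
  pos <- array(stats::rnorm(n * m * 3, 500, 100), c(n, m, 3))
  occ <- matrix(FALSE, n, m)
  if (!is.null(occlude)) {
    for (o in occlude) occ[o[1], o[2]] <- TRUE
    for (k in 1:3) {
      pk <- pos[, , k]
      pk[occ] <- NA
      pos[, , k] <- pk
    }
  }
  marker_series(pos, sprintf("M%d", seq_len(m)), rate, occ,
                start_time = start_time)
}

# bow trace straight from a b(t) vector
make_trace <- function(b, rate = 120) bowkin:::new_bow_trace(b, rate)

# sinusoidal bow coordinate: 0.5 + amp * sin(2 pi f t), duration in s
sine_trace <- function(f = 0.25, amp = 0.4, duration = 8, rate = 120) {
  t <- seq(0, duration, by = 1 / rate)
  make_trace(0.5 + amp * sin(2 * pi * f * t), rate)
}

rms <- function(x) sqrt(mean(x^2))
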