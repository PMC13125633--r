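# Spectral arc length (SPARC) movement-smoothness measure.

#' SPARC parameters
#'
#' @param f_max spectral cutoff in Hz (default 10): frequencies above it
#'   never contribute.
#' @param amp_threshold normalized amplitude threshold (default 0.05)
#'   used to adapt the cutoff to the signal's occupied band.
#' @param pad_factor zero-padding multiple for the FFT (default 4).
#' @return list of validated parameters.
#' @export
sparc_params <- function(f_max = 10, amp_threshold = 0.05, pad_factor = 4) {
  stopifnot(f_max > 0, amp_threshold > 0, amp_threshold < 1, pad_factor >= 1)
  list(f_max = f_max, amp_threshold = amp_threshold, pad_factor = pad_factor)
}

#' Spectral arc length of one speed profile
#'
#' Computes the negative arc length of the normalized magnitude spectrum
#' of a movement-speed profile: the spectrum is normalized by its value
#' at 0 Hz, restricted to an adaptive cutoff (the highest frequency not
#' above `f_max` where the normalized amplitude still reaches
#' `amp_threshold`), and its arc length is accumulated with the frequency
#' axis normalized by that cutoff. Values are negative; closer to zero
#' means smoother. The measure is invariant to amplitude scaling and to
#' time shifts of the profile.
#'
#' @param speed numeric vector, instantaneous speed within one stroke
#'   (any units); at least 8 samples, not identically zero.
#' @param rate sampling rate in Hz.
#' @param params a [sparc_params()] list.
#' @return SPARC value (dimensionless, negative), or `NA` for an
#'   all-zero profile.
#' @export
sparc <- function(speed, rate, params = sparc_params()) {
  if (length(speed) < 8) stop("sparc() needs at least 8 samples")
  if (all(speed == 0)) return(NA_real_)
  n_fft <- 2^ceiling(log2(length(speed) * params$pad_factor))
  spec <- Mod(stats::fft(c(speed, rep(0, n_fft - length(speed)))))
  spec <- spec[seq_len(n_fft %/% 2 + 1)]
  freq <- (seq_along(spec) - 1) * rate / n_fft
  specn <- spec / spec[1]
  in_band <- freq <= params$f_max
  occupied <- which(in_band & specn >= params$amp_threshold)
  i_cut <- max(occupied, 2L)
  f_cut <- freq[i_cut]
  sel <- seq_len(i_cut)
  df <- diff(freq[sel]) / f_cut
  dv <- diff(specn[sel])
  -sum(sqrt(df^2 + dv^2))
}

#' Mean per-stroke SPARC of a bow trace
#'
#' Computes [sparc()] on the absolute bow speed `|v|` of each stroke and
#' averages across strokes; strokes shorter than 8 frames are skipped.
#' Per-stroke computation keeps values in the band typical of discrete
#' reaching-like movements; a whole-trial spectrum would be far more
#' negative.
#'
#' @param trace a bow trace.
#' @param strokes stroke table from [segment_strokes()].
#' @param params a [sparc_params()] list.
#' @return mean SPARC across usable strokes, or `NA` if none.
#' @export
sparc_trial <- function(trace, strokes, params = sparc_params()) {
  if (nrow(strokes) == 0) return(NA_real_)
  vals <- vapply(seq_len(nrow(strokes)), function(k) {
    idx <- strokes$i_start[k]:strokes$i_end[k]
    if (length(idx) < 8) return(NA_real_)
    sp <- abs(trace$v[idx])
    if (all(sp == 0)) return(NA_real_)
    sparc(sp, trace$rate, params)
  }, 0)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}
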