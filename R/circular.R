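# Circular-statistics helpers used by the coordination-variability and
# synchronization metrics.

# floor applied to the mean resultant length before taking log; caps the
# circular SD of fully dispersed samples at sqrt(-2*log(CIRC_RBAR_MIN)) rad
CIRC_RBAR_MIN <- 1e-6

#' Mean resultant vector of a sample of angles
#'
#' @param theta angles in radians.
#' @return list with `rbar` (mean resultant length, in [0, 1]) and
#'   `mean` (circular mean angle, rad, in (-pi, pi]).
#' @export
circ_resultant <- function(theta) {
  c_ <- mean(cos(theta))
  s_ <- mean(sin(theta))
  list(rbar = sqrt(c_^2 + s_^2), mean = atan2(s_, c_))
}

#' Circular standard deviation
#'
#' `sqrt(-2 log(rbar))`, in degrees. A fully dispersed sample
#' (`rbar = 0`) is capped by flooring `rbar` at `1e-6`, giving a finite
#' maximum of about 301 degrees.
#'
#' @param theta angles in radians.
#' @return circular SD in degrees.
#' @export
circ_sd_deg <- function(theta) {
  rbar <- max(circ_resultant(theta)$rbar, CIRC_RBAR_MIN)
  sqrt(-2 * log(rbar)) * RAD2DEG
}

# wrap radians to [-pi, pi)
wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}
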