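#' Periodic inflow velocity waveform
#'
#' The inlet boundary condition is a periodic velocity signal expressed as a
#' truncated Fourier series,
#' \deqn{v(t) = a_0 + \sum_{k=1}^K a_k \cos(2\pi k t/\tau) + b_k \sin(2\pi k t/\tau).}
#' By default the coefficients are fitted to a half-sine systolic pulse
#' (peak `peak` m/s over the first `systole_fraction` of each cardiac cycle,
#' zero in diastole), a standard idealization of an aortic inflow pulse.
#' Coefficients may also be supplied directly via `cos_coef`/`sin_coef`.
#'
#' @param period Cardiac cycle length tau, s.
#' @param n_cycles Number of cycles the simulation should cover.
#' @param peak Peak systolic velocity, m/s.
#' @param systole_fraction Fraction of the cycle occupied by the pulse.
#' @param n_harmonics Number of Fourier harmonics K.
#' @param cos_coef,sin_coef Optional explicit coefficients (length K + 1,
#'   first entry the constant term / zero).
#' @return An object of class `inflow_waveform`.
#' @export
inflow_waveform <- function(period = 1.1, n_cycles = 3, peak = 0.5,
                            systole_fraction = 0.3, n_harmonics = 10,
                            cos_coef = NULL, sin_coef = NULL) {
  stopifnot(period > 0, n_cycles >= 1)
  if (is.null(cos_coef) != is.null(sin_coef))
    stop("provide both cos_coef and sin_coef, or neither")
  if (is.null(cos_coef)) {
    # Fourier coefficients of the half-sine pulse, by dense trapezoidal
    # quadrature over one period (deterministic; done once at construction)
    ng <- 4096
    tg <- (seq_len(ng) - 1) / ng * period
    ts <- systole_fraction * period
    v <- ifelse(tg <= ts, peak * sin(pi * tg / ts), 0)
    K <- n_harmonics
    cos_coef <- numeric(K + 1)
    sin_coef <- numeric(K + 1)
    cos_coef[1] <- mean(v)
    for (k in seq_len(K)) {
      cos_coef[k + 1] <- 2 * mean(v * cos(2 * pi * k * tg / period))
      sin_coef[k + 1] <- 2 * mean(v * sin(2 * pi * k * tg / period))
    }
  } else {
    if (length(cos_coef) != length(sin_coef))
      stop("cos_coef and sin_coef must have equal length")
  }
  structure(list(period = period, n_cycles = n_cycles,
                 cos_coef = cos_coef, sin_coef = sin_coef),
            class = "inflow_waveform")
}

#' Evaluate an inflow waveform
#'
#' @param waveform An [inflow_waveform()].
#' @param t Times, s.
#' @return Inflow velocities, m/s.
#' @export
waveform_velocity <- function(waveform, t) {
  ang <- 2 * pi * t / waveform$period
  v <- rep(waveform$cos_coef[1], length(t))
  K <- length(waveform$cos_coef) - 1
  for (k in seq_len(K))
    v <- v + waveform$cos_coef[k + 1] * cos(k * ang) +
             waveform$sin_coef[k + 1] * sin(k * ang)
  v
}

#' @export
print.inflow_waveform <- function(x, ...) {
  tg <- seq(0, x$period, length.out = 400)
  cat(sprintf(
    "inflow_waveform: period %.3f s, %d cycles, %d harmonics, peak %.3f m/s\n",
    x$period, x$n_cycles, length(x$cos_coef) - 1,
    max(waveform_velocity(x, tg))))
  invisible(x)
}
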