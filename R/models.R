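#' Circular difference in degrees
#'
#' Signed angular difference `a - b` wrapped to `[-180, 180)`.
#'
#' @param a,b Angles in degrees.
#' @return Wrapped difference in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

#' Double-Gaussian direction tuning model
#'
#' Two Gaussian lobes of common width `sigma` centred on the preferred
#' direction and on the null direction 180 degrees away, on a baseline:
#' `R(theta) = R0 + Rp exp(-d_p^2 / 2 sigma^2) + Rn exp(-d_n^2 / 2 sigma^2)`
#' with `d_p = theta - theta_p` and `d_n = theta - theta_p + 180`, both
#' taken as circular differences.
#'
#' @param theta_deg Stimulus direction(s), degrees.
#' @param R0 Baseline rate (Hz).
#' @param Rp Response amplitude at the preferred direction.
#' @param Rn Response amplitude at the null (opposite) direction.
#' @param theta_p Preferred direction, degrees.
#' @param sigma Tuning width, degrees.
#' @return Predicted rate(s), Hz.
#' @export
double_gaussian <- function(theta_deg, R0, Rp, Rn, theta_p, sigma) {
  dp <- circ_diff_deg(theta_deg, theta_p)
  dn <- circ_diff_deg(theta_deg + 180, theta_p)
  R0 + Rp * exp(-dp^2 / (2 * sigma^2)) + Rn * exp(-dn^2 / (2 * sigma^2))
}

#' Difference-of-Gaussians spatial-frequency tuning model
#'
#' Excitatory minus inhibitory Gaussian on a baseline:
#' `R(x) = R0 + Ke exp(-(x - mu_e)^2 / 2 sig_e^2)
#'            - Ki exp(-(x - mu_i)^2 / 2 sig_i^2)`.
#' The model is axis-agnostic; the pipeline fits it on a log2
#' spatial-frequency axis by default since the stimulus levels are
#' octave-spaced (see [fit_sf_tuning()]).
#'
#' @param x Spatial frequency in the fitting coordinate.
#' @param R0 Baseline rate.
#' @param Ke,Ki Excitatory / inhibitory amplitudes.
#' @param mu_e,mu_i Component centres.
#' @param sig_e,sig_i Component widths (> 0).
#' @return Predicted rate(s).
#' @export
dog_model <- function(x, R0, Ke, Ki, mu_e, mu_i, sig_e, sig_i) {
  R0 + Ke * exp(-(x - mu_e)^2 / (2 * sig_e^2)) -
       Ki * exp(-(x - mu_i)^2 / (2 * sig_i^2))
}

#' Hyperbolic-ratio (Naka-Rushton) contrast response model
#'
#' `R(c) = R0 + Rmax * c^n / (c50^n + c^n)`: a saturating contrast
#' response with semisaturation contrast `c50` and exponent `n`.
#'
#' @param contrast Stimulus contrast(s) in `(0, 1]`.
#' @param R0 Baseline rate.
#' @param Rmax Maximum evoked response.
#' @param n Exponent (slope of the rising phase).
#' @param c50 Semisaturation contrast.
#' @return Predicted rate(s).
#' @export
hyperbolic_ratio <- function(contrast, R0, Rmax, n, c50) {
  R0 + Rmax * contrast^n / (c50^n + contrast^n)
}

# Evoked-response amplitude (Hz above baseline) of a ground-truth unit for
# one stimulus row of a trial table. The novel checkerboard is a distinct
# class: its amplitude is the unit's novel_amp parameter.
unit_tuned_response <- function(unit, stim) {
  amp <- switch(stim$kind,
    drifting_grating = double_gaussian(stim$direction_deg, 0, unit$Rp,
                                       unit$Rn, unit$theta_p, unit$sigma),
    static_grating = hyperbolic_ratio(stim$contrast, 0, unit$Rmax,
                                      unit$n_exp, unit$c50),
    sf_noise = dog_model(log2(stim$sf_cpd), 0, unit$Ke, unit$Ki,
                         unit$mu_e, unit$mu_i, unit$sig_e, unit$sig_i),
    checkerboard = unit$novel_amp,
    stop("unknown stimulus kind: ", stim$kind))
  max(amp, 0)
}
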