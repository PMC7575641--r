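#' Epoched spike trains
#'
#' Per-trial spike times of one unit, relative to stimulus onset, within a
#' common epoch window.
#'
#' @param trials List of numeric vectors (one per trial), spike times in
#'   seconds relative to onset.
#' @param window Epoch window `c(start, end)` relative to onset, seconds.
#' @return An `epoched_spikes` object.
#' @export
epoched_spikes <- function(trials, window) {
  stopifnot(is.list(trials), length(window) == 2, window[1] < window[2])
  structure(list(trials = trials, window = window,
                 n_trials = length(trials)),
            class = "epoched_spikes")
}

#' @export
print.epoched_spikes <- function(x, ...) {
  cat(sprintf("<epoched_spikes> %d trials, window [%.2f, %.2f] s, %d spikes\n",
              x$n_trials, x$window[1], x$window[2],
              sum(lengths(x$trials))))
  invisible(x)
}

# Stimulus-locked response envelope: 20-ms linear ramp after onset,
# sustained at 1 through the stimulus (and through the oscillation window
# when the oscillation is enabled), exponential decay (tau = 100 ms) after.
response_envelope <- function(t, duration_s, sustain_until) {
  g <- numeric(length(t))
  up <- t >= 0 & t < 0.02
  g[up] <- t[up] / 0.02
  hold <- t >= 0.02 & t <= sustain_until
  g[hold] <- 1
  tail <- t > sustain_until
  g[tail] <- exp(-(t[tail] - sustain_until) / 0.1)
  g
}

# Instantaneous firing rate (Hz) of a ground-truth unit at epoch times t
# for one stimulus; clipped at zero.
unit_rate <- function(t, unit, stim, amp) {
  sustain <- stim$duration_s
  osc_on <- isTRUE(unit$osc_enabled) && unit$osc_duration > 0 &&
    unit$mod_depth > 0
  if (osc_on) sustain <- max(sustain, unit$osc_duration)
  g <- response_envelope(t, stim$duration_s, sustain)
  rate <- unit$baseline_rate + amp * g
  if (osc_on) {
    w <- t > 0 & t <= unit$osc_duration
    rate[w] <- unit$baseline_rate +
      amp * g[w] * (1 + unit$mod_depth * cos(2 * pi * unit$f_osc * t[w]))
  }
  pmax(rate, 0)
}

#' Simulate spike trains of one unit over a trial table
#'
#' Inhomogeneous-Poisson spikes by thinning: for each trial the rate is
#' `baseline + tuned_response(stimulus) * g(t)`, where `g(t)` is a
#' stimulus-locked envelope (20-ms ramp, sustained during the stimulus,
#' exponential decay after offset). When the unit's familiarity
#' oscillation is enabled, the evoked component is multiplied by
#' `1 + mod_depth * cos(2 pi f_osc t)` for `t` in `(0, osc_duration]`,
#' phase-locked to stimulus onset, and the envelope is sustained through
#' the oscillation window. Thinning uses the analytic upper bound
#' `baseline + amp * (1 + mod_depth)`, so the draw is exact.
#'
#' @param unit One ground-truth unit (single row of [sample_units()], or
#'   an equivalent list).
#' @param trials A `trial_table`.
#' @param epoch_window Window around onset, seconds; must include a
#'   pre-onset baseline (start <= 0) and end after the stimulus.
#' @param seed Integer seed.
#' @return An [epoched_spikes()] object with one element per trial row.
#' @export
simulate_spikes <- function(unit, trials, epoch_window = c(-0.5, 2.0),
                            seed = 1L) {
  if (length(epoch_window) != 2 || epoch_window[2] <= epoch_window[1]) {
    stop("`epoch_window` must be an increasing interval")
  }
  unit <- as.list(unit)
  set.seed(seed)
  w0 <- epoch_window[1]; w1 <- epoch_window[2]
  span <- w1 - w0
  out <- vector("list", nrow(trials))
  # column vectors once; per-trial data-frame row extraction is the
  # dominant cost over long protocols
  kindv <- trials$kind; dirv <- trials$direction_deg
  sfv <- trials$sf_cpd; tfv <- trials$tf_hz
  conv <- trials$contrast; durv <- trials$duration_s
  for (i in seq_len(nrow(trials))) {
    stim <- list(kind = kindv[i], direction_deg = dirv[i], sf_cpd = sfv[i],
                 tf_hz = tfv[i], contrast = conv[i], duration_s = durv[i])
    amp <- unit_tuned_response(unit, stim)
    rate_max <- unit$baseline_rate +
      amp * (1 + if (isTRUE(unit$osc_enabled)) unit$mod_depth else 0)
    n_cand <- stats::rpois(1, rate_max * span)
    if (n_cand == 0) { out[[i]] <- numeric(0); next }
    t_cand <- sort(stats::runif(n_cand, w0, w1))
    keep <- stats::runif(n_cand) < unit_rate(t_cand, unit, stim, amp) / rate_max
    out[[i]] <- t_cand[keep]
  }
  epoched_spikes(out, epoch_window)
}

# 1/f ("pink") noise via spectral shaping; unit variance before scaling.
pink_noise <- function(n) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- abs(fft_freqs(n))
  f[1] <- f[2]                     # keep DC finite
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(y))
}

#' Simulate a multichannel LFP recording over a trial table
#'
#' Pink-noise background per channel, plus a stimulus-evoked negative
#' transient (Gaussian-shaped, peaking 50 ms after onset) whose amplitude
#' is most negative at `layer4_channel` and decays exponentially with
#' channel distance — emulating the thalamorecipient layer-IV current
#' sink used for channel selection. For `condition = "post_familiar"` a
#' decaying theta burst (default 6 Hz, 1/e decay 0.5 s) with
#' trial-consistent phase (cosine at onset) is added with the same depth
#' profile. An optional 60-Hz sinusoid emulates line contamination.
#'
#' @param trials A `trial_table`.
#' @param n_channels Number of probe channels (depth order).
#' @param fs_hz Sampling rate; must be >= 200 Hz to represent the 2-80 Hz
#'   analysis range.
#' @param layer4_channel Index (1-based) of the layer-IV channel.
#' @param condition Condition label; the theta burst is added only for
#'   `"post_familiar"`.
#' @param seed Integer seed.
#' @param noise_sd Pink-noise SD, microvolts.
#' @param evoked_amp Peak amplitude of the evoked deflection (positive
#'   number; applied negatively), microvolts.
#' @param theta_amp Theta-burst amplitude, microvolts.
#' @param theta_f Theta-burst frequency, Hz.
#' @param line_amp 60-Hz contaminant amplitude, microvolts (0 disables).
#' @param tail_s Seconds of recording kept after the last onset.
#' @return An `lfp_recording`: list with `data` (time x channels matrix),
#'   `fs_hz`, `n_channels`.
#' @export
simulate_lfp <- function(trials, n_channels = 64, fs_hz = 1000,
                         layer4_channel = 20, condition = "pre",
                         seed = 1L, noise_sd = 20, evoked_amp = 100,
                         theta_amp = 40, theta_f = 6, line_amp = 0,
                         tail_s = 3) {
  if (fs_hz < 200) {
    stop("`fs_hz` must be >= 200 Hz to represent the 2-80 Hz bands")
  }
  if (layer4_channel < 1 || layer4_channel > n_channels) {
    stop("`layer4_channel` must index a channel")
  }
  set.seed(seed)
  n_t <- ceiling((max(trials$onset_s) + tail_s) * fs_hz)
  tt <- (seq_len(n_t) - 1) / fs_hz
  depth_profile <- exp(-abs(seq_len(n_channels) - layer4_channel) / 6)

  evoked <- numeric(n_t)
  theta <- numeric(n_t)
  for (on in trials$onset_s) {
    rel <- tt - on
    win <- rel >= 0 & rel <= 0.3
    evoked[win] <- evoked[win] - exp(-(rel[win] - 0.05)^2 / (2 * 0.02^2))
    if (identical(condition, "post_familiar")) {
      wth <- rel >= 0 & rel <= 1.5
      theta[wth] <- theta[wth] +
        cos(2 * pi * theta_f * rel[wth]) * exp(-rel[wth] / 0.5)
    }
  }
  common <- evoked_amp * evoked + theta_amp * theta
  data <- matrix(0, n_t, n_channels)
  for (ch in seq_len(n_channels)) {
    bg <- if (noise_sd > 0) noise_sd * pink_noise(n_t) else numeric(n_t)
    data[, ch] <- bg + depth_profile[ch] * common
  }
  if (line_amp > 0) {
    data <- data + line_amp * sin(2 * pi * 60 * tt)
  }
  structure(list(data = data, fs_hz = fs_hz, n_channels = n_channels),
            class = "lfp_recording")
}
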