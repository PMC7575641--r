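# Shared fixture builders; everything is generated in code at test time.

# A deterministic ground-truth unit (list form) with controllable fields.
fixture_unit <- function(baseline_rate = 3, Rp = 25, Rn = 8, theta_p = 90,
                         sigma = 25, Ke = 20, Ki = 0, mu_e = log2(0.05),
                         mu_i = log2(7.5e-3), sig_e = 1.2, sig_i = 1,
                         Rmax = 20, c50 = 0.3, n_exp = 2, novel_amp = 15,
                         f_osc = 6, mod_depth = 0, osc_duration = 0,
                         osc_enabled = FALSE) {
  list(baseline_rate = baseline_rate, Rp = Rp, Rn = Rn, theta_p = theta_p,
       sigma = sigma, Ke = Ke, Ki = Ki, mu_e = mu_e, mu_i = mu_i,
       sig_e = sig_e, sig_i = sig_i, Rmax = Rmax, c50 = c50, n_exp = n_exp,
       novel_amp = novel_amp, f_osc = f_osc, mod_depth = mod_depth,
       osc_duration = osc_duration, osc_enabled = osc_enabled)
}

# Noise-free tuning curve straight from a model evaluation.
fixture_curve <- function(levels, means, level_var = "direction_deg") {
  structure(list(levels = levels,
                 responses = as.list(means),
                 mean = means,
                 sem = rep(0, length(means)),
                 level_var = level_var,
                 response_window = c(0.05, 0.5)),
            class = "tuning_curve")
}

# LFP epochs built directly as an array: per-channel evoked deflection
# profile plus optional phase-locked theta burst and Gaussian noise.
fixture_lfp_epochs <- function(n_trials = 10, n_channels = 16,
                               layer4 = 6, fs = 1000,
                               window = c(-0.5, 1.0),
                               deflect_amp = 100, noise_sd = 0,
                               theta_amp = 0, theta_f = 6,
                               theta_decay = 0.5) {
  times <- seq(window[1], window[2], by = 1 / fs)
  profile <- exp(-abs(seq_len(n_channels) - layer4) / 4)
  deflect <- -deflect_amp * exp(-(times - 0.05)^2 / (2 * 0.02^2)) *
    (times >= 0)
  theta <- if (theta_amp > 0) {
    theta_amp * cos(2 * pi * theta_f * times) *
      exp(-pmax(times, 0) / theta_decay) * (times >= 0)
  } else {
    numeric(length(times))
  }
  arr <- array(0, dim = c(n_trials, n_channels, length(times)))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_channels)) {
      arr[tr, ch, ] <- profile[ch] * (deflect + theta) +
        stats::rnorm(length(times), sd = noise_sd)
    }
  }
  structure(list(data = arr, times = times, fs_hz = fs, window = window,
                 n_trials = n_trials, n_channels = n_channels),
            class = "lfp_epochs")
}

# Homogeneous-Poisson epoched spikes at a constant rate.
fixture_poisson_spikes <- function(rate_hz, n_trials,
                                   window = c(-0.5, 1.0), seed = 1) {
  set.seed(seed)
  span <- diff(window)
  trials <- lapply(seq_len(n_trials), function(i) {
    n <- stats::rpois(1, rate_hz * span)
    sort(stats::runif(n, window[1], window[2]))
  })
  epoched_spikes(trials, window)
}
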