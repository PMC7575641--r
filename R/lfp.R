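#' Preprocess raw LFP: anti-aliased downsampling to 1 kHz and 60-Hz removal
#'
#' Decimates a multichannel trace to 1 kHz after FIR anti-alias
#' filtering, then removes 60-Hz line noise with a symmetric linear-phase
#' FIR band-stop filter applied forward and backward (`signal::filtfilt`),
#' so the net group delay is zero.
#'
#' @param raw Numeric matrix (time x channels) or vector.
#' @param fs_in Input sampling rate, Hz; must be >= 1000 and an integer
#'   multiple of 1000.
#' @param notch Apply the 60-Hz band-stop stage.
#' @return An `lfp_recording` at 1 kHz.
#' @export
preprocess_lfp <- function(raw, fs_in, notch = TRUE) {
  if (inherits(raw, "lfp_recording")) { fs_in <- raw$fs_hz; raw <- raw$data }
  if (is.null(dim(raw))) raw <- matrix(raw, ncol = 1)
  if (fs_in < 1000) stop("`fs_in` must be >= 1 kHz")
  q <- fs_in / 1000
  if (abs(q - round(q)) > 1e-9) {
    stop("`fs_in` must be an integer multiple of 1000 Hz")
  }
  q <- as.integer(round(q))
  out <- raw
  if (q > 1) {
    # FIR low-pass at 0.8 * target Nyquist, zero-phase, then subsample
    aa <- signal::fir1(96, 0.8 * 500 / (fs_in / 2))
    out <- apply(out, 2, function(x) signal::filtfilt(aa, x))
    out <- out[seq(1, nrow(out), by = q), , drop = FALSE]
  }
  if (notch) {
    bs <- signal::fir1(500, c(55, 65) / 500, type = "stop")
    out <- apply(out, 2, function(x) signal::filtfilt(bs, x))
  }
  structure(list(data = out, fs_hz = 1000, n_channels = ncol(out)),
            class = "lfp_recording")
}

#' Epoch a continuous LFP recording around stimulus onsets
#'
#' @param rec An `lfp_recording` (1 kHz; see [preprocess_lfp()]).
#' @param onsets_s Stimulus onset times, seconds.
#' @param window Epoch window around onset, seconds; must include at
#'   least 0.5 s of pre-onset baseline.
#' @return An `lfp_epochs` object: `data` array (trials x channels x
#'   time), `times` (s, relative to onset), `fs_hz`.
#' @export
epoch_lfp <- function(rec, onsets_s, window = c(-0.5, 2.0)) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (window[1] > -0.5) {
    stop("epoch window must include >= 0.5 s pre-onset baseline")
  }
  fs <- rec$fs_hz
  i0 <- round(window[1] * fs); i1 <- round(window[2] * fs)
  idx_rel <- i0:i1
  times <- idx_rel / fs
  keep <- vapply(onsets_s, function(on) {
    s <- round(on * fs) + 1
    s + i0 >= 1 && s + i1 <= nrow(rec$data)
  }, logical(1))
  onsets_s <- onsets_s[keep]
  if (length(onsets_s) == 0) stop("no complete epochs inside the recording")
  arr <- array(NA_real_,
               dim = c(length(onsets_s), rec$n_channels, length(idx_rel)))
  for (i in seq_along(onsets_s)) {
    s <- round(onsets_s[i] * fs) + 1
    arr[i, , ] <- t(rec$data[s + idx_rel, , drop = FALSE])
  }
  structure(list(data = arr, times = times, fs_hz = fs,
                 window = window, n_trials = length(onsets_s),
                 n_channels = rec$n_channels),
            class = "lfp_epochs")
}

#' Identify the layer-IV channel
#'
#' The channel whose trial-averaged trace attains the strongest (most
#' negative) deflection within the first 100 ms after stimulus onset —
#' the thalamorecipient current sink. Ties break to the shallowest
#' channel (smallest index).
#'
#' @param epochs An `lfp_epochs` object.
#' @return Channel index (1-based).
#' @export
find_layer4_channel <- function(epochs) {
  stopifnot(inherits(epochs, "lfp_epochs"))
  if (epochs$n_trials < 1) stop("no trials in epochs")
  sel <- epochs$times > 0 & epochs$times <= 0.1
  avg <- apply(epochs$data[, , sel, drop = FALSE], c(2, 3), mean)
  mins <- apply(avg, 1, min)
  if (all(mins == mins[1]) && length(mins) > 1 && diff(range(avg)) == 0) {
    stop("all-channel traces are constant; layer-IV channel indeterminate")
  }
  which.min(mins)[1]
}

#' Complex Morlet wavelet family
#'
#' `n` complex Morlet wavelets with centre frequencies log-spaced from
#' `f_min` to `f_max` and cycle counts log-spaced from `cycles_min` to
#' `cycles_max` across the family (more cycles at higher frequencies:
#' the usual time-frequency precision trade-off). Each wavelet is
#' normalised to unit energy.
#'
#' @param f_min,f_max Frequency range, Hz.
#' @param n Number of wavelets.
#' @param cycles_min,cycles_max Cycle-count range.
#' @param fs_hz Sampling rate the wavelets are built for.
#' @return A `wavelet_family`: list with `freqs`, `cycles`, `wavelets`
#'   (list of complex vectors, odd length, centred).
#' @export
wavelet_family <- function(f_min = 2, f_max = 80, n = 40,
                           cycles_min = 3, cycles_max = 10, fs_hz = 1000) {
  stopifnot(f_min > 0, f_max > f_min, n >= 2)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n))
  cycles <- exp(seq(log(cycles_min), log(cycles_max), length.out = n))
  wavelets <- lapply(seq_len(n), function(i) {
    sd_t <- cycles[i] / (2 * pi * freqs[i])
    half <- ceiling(4 * sd_t * fs_hz)
    t <- (-half:half) / fs_hz
    w <- exp(2i * pi * freqs[i] * t) * exp(-t^2 / (2 * sd_t^2))
    w / sqrt(sum(Mod(w)^2))
  })
  structure(list(freqs = freqs, cycles = cycles, wavelets = wavelets,
                 fs_hz = fs_hz),
            class = "wavelet_family")
}

# Same-length complex convolution with reflection padding at the edges.
conv_reflect <- function(x, w) {
  half <- (length(w) - 1) / 2
  pad <- min(half, length(x) - 1)
  xe <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  n <- length(xe) + length(w) - 1
  X <- stats::fft(c(xe, rep(0, n - length(xe))))
  W <- stats::fft(c(w, rep(0, n - length(w))))
  full <- stats::fft(X * W, inverse = TRUE) / n
  full[(pad + half + 1):(pad + half + length(x))]
}

tf_map <- function(freqs, times, values, kind, baseline_window = NULL) {
  structure(list(freqs = freqs, times = times, values = values,
                 kind = kind, baseline_window = baseline_window),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map:%s> %d freqs (%.3g-%.3g Hz) x %d times (%.2f..%.2f s)\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Wavelet time-frequency power, dB-normalised to a pre-onset baseline
#'
#' Convolves each wavelet of the family with the trial-averaged (evoked)
#' LFP of one channel, squares the magnitude, and normalises per
#' frequency in decibels against the mean power in a pre-onset baseline
#' window: `10 log10(power / baseline mean)`. Set `evoked = FALSE` to
#' average single-trial (induced) power before normalising instead.
#'
#' @param epochs An `lfp_epochs` object.
#' @param channel Channel index (typically [find_layer4_channel()]).
#' @param baseline_window Baseline interval, seconds relative to onset;
#'   must be pre-onset and inside the epoch.
#' @param family A [wavelet_family()]; default 40 wavelets, 2-80 Hz.
#' @param evoked Convolve the trial average (default) or average
#'   single-trial power.
#' @return A `tf_map` with `kind = "power_db"`.
#' @export
tf_power <- function(epochs, channel, baseline_window = c(-0.5, -0.1),
                     family = NULL, evoked = TRUE) {
  stopifnot(inherits(epochs, "lfp_epochs"))
  if (baseline_window[2] > 0 || baseline_window[1] < epochs$window[1]) {
    stop("`baseline_window` must be pre-onset and inside the epoch")
  }
  if (is.null(family)) family <- wavelet_family(fs_hz = epochs$fs_hz)
  base_idx <- epochs$times >= baseline_window[1] &
              epochs$times <= baseline_window[2]
  nf <- length(family$freqs)
  pow <- matrix(NA_real_, nf, length(epochs$times))
  if (evoked) {
    trace <- apply(epochs$data[, channel, , drop = FALSE], 3, mean)
    for (i in seq_len(nf)) {
      pow[i, ] <- Mod(conv_reflect(trace, family$wavelets[[i]]))^2
    }
  } else {
    for (i in seq_len(nf)) {
      acc <- numeric(length(epochs$times))
      for (tr in seq_len(epochs$n_trials)) {
        acc <- acc + Mod(conv_reflect(epochs$data[tr, channel, ],
                                      family$wavelets[[i]]))^2
      }
      pow[i, ] <- acc / epochs$n_trials
    }
  }
  base <- rowMeans(pow[, base_idx, drop = FALSE])
  if (any(base <= 0)) stop("zero baseline power; cannot dB-normalise")
  db <- 10 * log10(pow / base)
  tf_map(family$freqs, epochs$times, db, "power_db", baseline_window)
}

#' Named canonical frequency bands
#'
#' theta 4-8, alpha 8-12, beta 12-30, low gamma 30-50, high gamma
#' 50-80 Hz.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
lfp_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
       low_gamma = c(30, 50), high_gamma = c(50, 80))
}

#' Mean band value of a time-frequency map
#'
#' Mean of the map over frequencies inside `band` and times inside
#' `window` (default the first second after onset).
#'
#' @param map A `tf_map`.
#' @param band `c(lo, hi)` in Hz, or a name from [lfp_bands()].
#' @param window Time window, seconds.
#' @return Scalar (dB for power maps; coherence for ITPC maps).
#' @export
band_power <- function(map, band, window = c(0, 1)) {
  stopifnot(inherits(map, "tf_map"))
  if (is.character(band)) band <- lfp_bands()[[band]]
  fi <- map$freqs >= band[1] & map$freqs <= band[2]
  ti <- map$times >= window[1] & map$times <= window[2]
  if (!any(fi) || !any(ti)) stop("empty band/window selection")
  mean(map$values[fi, ti])
}

#' Intertrial phase coherence
#'
#' For each wavelet with centre frequency at most `f_max_itpc`, extracts
#' the per-trial instantaneous phase by convolution and computes
#' `ITPC(t, f) = | mean over trials of exp(i * phase) |`: 1 for perfect
#' phase locking across trials, ~1/sqrt(N) for random phases. Reported
#' by convention over the first 0.5 s after onset via
#' [band_power()]-style summaries; frequencies above `f_max_itpc`
#' (default 40 Hz) are excluded because trial counts and the display
#' refresh limit phase estimation there.
#'
#' @param epochs An `lfp_epochs` object with at least 2 trials.
#' @param channel Channel index.
#' @param family A [wavelet_family()]; default 40 wavelets 2-80 Hz.
#' @param f_max_itpc Upper frequency limit, Hz.
#' @return A `tf_map` with `kind = "itpc"`, values in `[0, 1]`.
#' @export
itpc <- function(epochs, channel, family = NULL, f_max_itpc = 40) {
  stopifnot(inherits(epochs, "lfp_epochs"))
  if (epochs$n_trials < 2) {
    stop("ITPC requires >= 2 trials (degenerate at 1)")
  }
  if (is.null(family)) family <- wavelet_family(fs_hz = epochs$fs_hz)
  keep <- family$freqs <= f_max_itpc
  freqs <- family$freqs[keep]
  wl <- family$wavelets[keep]
  vals <- matrix(NA_real_, length(freqs), length(epochs$times))
  for (i in seq_along(wl)) {
    acc <- complex(real = numeric(length(epochs$times)))
    for (tr in seq_len(epochs$n_trials)) {
      z <- conv_reflect(epochs$data[tr, channel, ], wl[[i]])
      acc <- acc + z / Mod(z)
    }
    vals[i, ] <- pmin(Mod(acc) / epochs$n_trials, 1)
  }
  tf_map(freqs, epochs$times, vals, "itpc")
}

#' Export a time-frequency map as TSV
#'
#' Long-format table (`freq_hz`, `time_s`, `value`) with the map kind in
#' a header comment.
#'
#' @param map A `tf_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_map <- function(map, path) {
  df <- data.frame(freq_hz = rep(map$freqs, times = length(map$times)),
                   time_s = rep(map$times, each = length(map$freqs)),
                   value = as.numeric(map$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", map$kind), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
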