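#' Stimulus specification
#'
#' A single visual stimulus as parameterised in the experimental protocols:
#' a drifting or static sinusoidal grating, spatial-frequency band-pass
#' filtered white noise, or a checkerboard (the novel-stimulus class label).
#' Only the parameters relevant to `kind` are non-`NA`.
#'
#' @param kind One of `"drifting_grating"`, `"static_grating"`, `"sf_noise"`,
#'   `"checkerboard"`.
#' @param direction_deg Drift / orientation direction in degrees, in
#'   `[0, 360)`. Gratings only.
#' @param sf_cpd Spatial frequency in cycles per degree (> 0). For
#'   `"sf_noise"` this is the band centre.
#' @param tf_hz Temporal frequency in Hz (>= 0; 0 for static stimuli).
#' @param contrast Michelson contrast in `(0, 1]`.
#' @param duration_s Presentation duration in seconds (> 0).
#' @return A `stimulus_spec` object (named list).
#' @examples
#' stimulus_spec("drifting_grating", direction_deg = 30, sf_cpd = 0.04,
#'               tf_hz = 2, contrast = 1, duration_s = 0.4)
#' @export
stimulus_spec <- function(kind,
                          direction_deg = NA_real_,
                          sf_cpd = NA_real_,
                          tf_hz = NA_real_,
                          contrast = NA_real_,
                          duration_s = 0.5) {
  kind <- match.arg(kind, c("drifting_grating", "static_grating",
                            "sf_noise", "checkerboard"))
  if (!is.na(direction_deg)) {
    direction_deg <- direction_deg %% 360
  }
  if (!is.na(sf_cpd) && sf_cpd <= 0) {
    stop("`sf_cpd` must be positive")
  }
  if (!is.na(contrast) && (contrast <= 0 || contrast > 1)) {
    stop("`contrast` must be in (0, 1]")
  }
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive")
  }
  structure(list(kind = kind, direction_deg = direction_deg,
                 sf_cpd = sf_cpd, tf_hz = tf_hz, contrast = contrast,
                 duration_s = duration_s),
            class = "stimulus_spec")
}

# One trial-table row from a stimulus spec; internal.
spec_row <- function(spec) {
  data.frame(kind = spec$kind,
             direction_deg = spec$direction_deg,
             sf_cpd = spec$sf_cpd,
             tf_hz = spec$tf_hz,
             contrast = spec$contrast,
             duration_s = spec$duration_s,
             stringsAsFactors = FALSE)
}

check_iti <- function(iti_range_s) {
  if (length(iti_range_s) != 2 || any(!is.finite(iti_range_s)) ||
      iti_range_s[1] <= 0 || iti_range_s[2] < iti_range_s[1]) {
    stop("`iti_range_s` must be a positive, non-inverted interval")
  }
  iti_range_s
}

# Onsets from uniform intertrial-interval draws; the first onset sits one
# ITI draw after the session origin so every gap (including the first) is a
# draw from the stated range.
draw_onsets <- function(n, iti_range_s) {
  itis <- stats::runif(n, iti_range_s[1], iti_range_s[2])
  cumsum(itis)
}

finish_trial_table <- function(stim_rows, condition, iti_range_s, seed) {
  set.seed(seed)
  n <- nrow(stim_rows)
  out <- cbind(data.frame(trial_index = seq_len(n),
                          onset_s = draw_onsets(n, iti_range_s)),
               stim_rows)
  out$condition <- condition
  attr(out, "iti_range_s") <- iti_range_s
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Build a familiarity (perceptual-experience) protocol
#'
#' Repeated presentation of one identical stimulus, as used to induce
#' visual familiarity: `n_per_day` presentations on each of `n_days`
#' days, with interstimulus intervals drawn uniformly from `iti_range_s`.
#' Days are concatenated on a single time axis (within-day timing is what
#' the epoch-based analyses consume).
#'
#' @param n_per_day Presentations per day (>= 1).
#' @param n_days Number of days (>= 1).
#' @param spec A [stimulus_spec()] describing the familiar stimulus; the
#'   default is the standard familiar grating (30 deg drifting grating,
#'   0.04 cpd, 2 Hz, full contrast, 0.4 s).
#' @param iti_range_s Interstimulus-interval range in seconds.
#' @param condition Condition tag stored on every row.
#' @param seed Integer seed; the protocol is reproducible under it.
#' @return A `trial_table` data frame with columns `trial_index`, `onset_s`,
#'   the stimulus parameters, and `condition`.
#' @examples
#' tt <- build_familiarity_protocol(200, 4, seed = 1)
#' nrow(tt)  # 800
#' @export
build_familiarity_protocol <- function(n_per_day, n_days,
                                       spec = stimulus_spec(
                                         "drifting_grating",
                                         direction_deg = 30, sf_cpd = 0.04,
                                         tf_hz = 2, contrast = 1,
                                         duration_s = 0.4),
                                       iti_range_s = c(3, 5),
                                       condition = "pre",
                                       seed = 1L) {
  if (!is.numeric(n_per_day) || n_per_day < 1 ||
      !is.numeric(n_days) || n_days < 1) {
    stop("`n_per_day` and `n_days` must be counts >= 1")
  }
  check_iti(iti_range_s)
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- as.integer(n_per_day) * as.integer(n_days)
  rows <- spec_row(spec)[rep(1L, n), , drop = FALSE]
  rownames(rows) <- NULL
  out <- finish_trial_table(rows, condition, iti_range_s, seed)
  out$day <- rep(seq_len(n_days), each = as.integer(n_per_day))
  out
}

#' Standard tuning-protocol level sets
#'
#' The fixed stimulus levels of the three tuning protocols: 12 drift
#' directions at 30 degree spacing, 6 octave-spaced spatial-frequency band
#' centres, and 5 contrast levels.
#'
#' @param kind `"orientation"`, `"sf"`, or `"contrast"`.
#' @return Numeric vector of levels.
#' @export
tuning_levels <- function(kind) {
  switch(match.arg(kind, c("orientation", "sf", "contrast")),
         orientation = seq(0, 330, by = 30),
         sf = c(7.5e-3, 0.015, 0.03, 0.06, 0.12, 0.24),
         contrast = c(0.0625, 0.125, 0.25, 0.5, 1.0))
}

#' Build a tuning protocol
#'
#' Balanced pseudorandom protocol for one of the three tuning experiments:
#' orientation (12 directions of a drifting grating, 0.04 cpd, 2 Hz, full
#' contrast, 0.5 s), spatial frequency (6 band-pass noise levels, new
#' exemplar per trial, intertrial interval at least 4 s to avoid
#' adaptation), or contrast (vertical static grating at 5 contrasts).
#' Every level appears exactly `n_repeats` times, in a seeded pseudorandom
#' order.
#'
#' @param kind `"orientation"`, `"sf"`, or `"contrast"`.
#' @param n_repeats Repeats per level (>= 1).
#' @param iti_range_s Intertrial-interval range in seconds; defaults to
#'   3-5 s for orientation/contrast and 4-6 s for spatial frequency.
#' @param condition Condition tag (`"tuning"` by default; the cohort
#'   generator relabels it per recording condition).
#' @param seed Integer seed.
#' @return A `trial_table` data frame (see [build_familiarity_protocol()]).
#' @examples
#' tt <- build_tuning_protocol("sf", n_repeats = 20, seed = 3)
#' table(tt$sf_cpd)  # each of the 6 levels exactly 20 times
#' @export
build_tuning_protocol <- function(kind, n_repeats,
                                  iti_range_s = NULL,
                                  condition = "tuning",
                                  seed = 1L) {
  kind <- match.arg(kind, c("orientation", "sf", "contrast"))
  if (!is.numeric(n_repeats) || n_repeats < 1) {
    stop("`n_repeats` must be a count >= 1")
  }
  if (is.null(iti_range_s)) {
    iti_range_s <- if (kind == "sf") c(4, 6) else c(3, 5)
  }
  check_iti(iti_range_s)
  if (kind == "sf" && iti_range_s[1] < 4) {
    stop("spatial-frequency tuning requires intertrial intervals >= 4 s")
  }
  levels <- tuning_levels(kind)
  specs <- switch(kind,
    orientation = lapply(levels, function(d)
      stimulus_spec("drifting_grating", direction_deg = d, sf_cpd = 0.04,
                    tf_hz = 2, contrast = 1, duration_s = 0.5)),
    sf = lapply(levels, function(s)
      stimulus_spec("sf_noise", sf_cpd = s, tf_hz = 0, contrast = 1,
                    duration_s = 0.5)),
    contrast = lapply(levels, function(cc)
      stimulus_spec("static_grating", direction_deg = 0, sf_cpd = 0.04,
                    tf_hz = 0, contrast = cc, duration_s = 0.5)))
  rows <- do.call(rbind, lapply(specs, spec_row))
  set.seed(seed)
  order_idx <- sample(rep(seq_along(levels), times = as.integer(n_repeats)))
  rows <- rows[order_idx, , drop = FALSE]
  rownames(rows) <- NULL
  # finish_trial_table re-seeds, so the level order above and the ITI draws
  # are drawn from independent, reproducible streams
  finish_trial_table(rows, condition, iti_range_s, seed + 1L)
}

#' Octave-symmetric band edges for the standard spatial-frequency set
#'
#' The protocol specifies only band centres; edges are placed at the
#' geometric (half-octave) midpoints so that adjacent bands of the
#' octave-spaced centre set abut exactly without overlapping.
#'
#' @param centers_cpd Band centres in cycles/degree.
#' @return A data frame with `center_cpd`, `lo_cpd`, `hi_cpd`.
#' @export
sf_noise_bands <- function(centers_cpd = tuning_levels("sf")) {
  data.frame(center_cpd = centers_cpd,
             lo_cpd = centers_cpd / sqrt(2),
             hi_cpd = centers_cpd * sqrt(2))
}

#' Spatial-frequency band-pass filtered white-noise image
#'
#' Generates the band-limited noise stimulus: white noise filtered in the
#' 2-D Fourier domain with a raised-cosine annular mask over radial spatial
#' frequency, then rescaled to luminance in `[0, 1]` with mean exactly 0.5
#' (the DC component is zeroed and amplitudes scaled symmetrically, so the
#' mid-grey mean is preserved across seeds). A fresh exemplar should be
#' drawn per trial (`seed` per trial).
#'
#' @param image_shape_px Integer pair, image height and width in pixels.
#' @param deg_per_px Degrees of visual angle per pixel (> 0).
#' @param band_cpd Pass band `(lo, hi)` in cycles/degree; must lie below
#'   the spatial Nyquist frequency `1 / (2 * deg_per_px)`.
#' @param seed Integer seed.
#' @param transition_octaves Width of the raised-cosine roll-off on each
#'   side of the band, in octaves (hard edges ring; default 0.5).
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_sf_filtered_noise <- function(image_shape_px, deg_per_px, band_cpd,
                                   seed = 1L, transition_octaves = 0.5) {
  stopifnot(length(image_shape_px) == 2, all(image_shape_px >= 8))
  if (!is.finite(deg_per_px) || deg_per_px <= 0) {
    stop("`deg_per_px` must be positive")
  }
  nyq <- 1 / (2 * deg_per_px)
  if (length(band_cpd) != 2 || band_cpd[1] < 0 || band_cpd[2] <= band_cpd[1]) {
    stop("`band_cpd` must be an increasing pair")
  }
  if (band_cpd[2] > nyq) {
    stop(sprintf("band upper edge %.4g cpd exceeds spatial Nyquist %.4g cpd",
                 band_cpd[2], nyq))
  }
  nr <- as.integer(image_shape_px[1])
  nc <- as.integer(image_shape_px[2])
  set.seed(seed)
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)

  fy <- fft_freqs(nr) / deg_per_px   # cycles/deg along rows
  fx <- fft_freqs(nc) / deg_per_px
  radial <- sqrt(outer(fy^2, fx^2, `+`))
  mask <- raised_cosine_annulus(radial, band_cpd[1], band_cpd[2],
                                transition_octaves)

  spec <- stats::fft(noise) * mask
  img <- Re(stats::fft(spec, inverse = TRUE)) / (nr * nc)
  img <- img - mean(img)
  peak <- max(abs(img))
  if (peak == 0) return(matrix(0.5, nr, nc))
  0.5 + 0.5 * img / peak
}

# Normalised FFT sample frequencies in cycles/sample (two-sided).
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Annular raised-cosine mask in log2-frequency: 1 inside [lo, hi], cosine
# roll-off over `trans` octaves, 0 beyond. lo = 0 degenerates to low-pass.
raised_cosine_annulus <- function(f, lo, hi, trans) {
  m <- matrix(0, nrow(f), ncol(f))
  pos <- f > 0
  lf <- log2(f[pos])
  hi_l <- log2(hi)
  up <- rep(1, sum(pos))
  up[lf > hi_l] <- 0.5 * (1 + cos(pi * pmin((lf[lf > hi_l] - hi_l) / trans, 1)))
  lo_w <- rep(1, sum(pos))
  if (lo > 0) {
    lo_l <- log2(lo)
    below <- lf < lo_l
    lo_w[below] <- 0.5 * (1 + cos(pi * pmin((lo_l - lf[below]) / trans, 1)))
  }
  m[pos] <- up * lo_w
  m
}

#' Radially averaged amplitude spectrum of an image
#'
#' Diagnostic used to verify the spectral concentration of the filtered
#' noise stimuli: amplitude spectrum averaged over annuli of radial
#' spatial frequency.
#'
#' @param img Numeric matrix.
#' @param deg_per_px Degrees per pixel.
#' @param n_bins Number of radial bins.
#' @return Data frame with `freq_cpd` (bin centre) and `amplitude`.
#' @export
radial_spectrum <- function(img, deg_per_px, n_bins = 40) {
  nr <- nrow(img); nc <- ncol(img)
  amp <- Mod(stats::fft(img - mean(img)))
  fy <- fft_freqs(nr) / deg_per_px
  fx <- fft_freqs(nc) / deg_per_px
  radial <- sqrt(outer(fy^2, fx^2, `+`))
  fmax <- min(max(abs(fy)), max(abs(fx)))
  keep <- radial > 0 & radial <= fmax
  bins <- cut(radial[keep], breaks = seq(0, fmax, length.out = n_bins + 1))
  mean_amp <- tapply(amp[keep], bins, mean)
  centers <- (seq(0, fmax, length.out = n_bins + 1)[-1] +
              seq(0, fmax, length.out = n_bins + 1)[-(n_bins + 1)]) / 2
  data.frame(freq_cpd = centers, amplitude = as.numeric(mean_amp))
}

#' Write a trial table to CSV
#'
#' @param trials A `trial_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  cols <- c("trial_index", "onset_s", "kind", "direction_deg", "sf_cpd",
            "tf_hz", "contrast", "duration_s", "condition")
  utils::write.csv(as.data.frame(trials)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#'
#' @param path CSV path.
#' @return A `trial_table` data frame.
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}
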