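#' Peristimulus time histogram with Gaussian smoothing
#'
#' Pools spike times across trials into 10-ms bins, converts to rate in
#' Hz (`counts / (n_trials * bin)`), and smooths with a Gaussian kernel
#' of 100-ms width (width taken as the kernel FWHM, i.e. SD ~ 42.5 ms;
#' see the methods vignette for why an SD reading would erase
#' theta-locked structure). The kernel is renormalised at the epoch
#' edges so smoothing conserves area.
#'
#' @param spikes An [epoched_spikes()] object.
#' @param bin_s Bin width, seconds.
#' @param kernel_width_s Gaussian kernel FWHM, seconds (0 disables
#'   smoothing).
#' @return A `psth`: list with `times` (bin centres, s relative to
#'   onset), `rate` (raw, Hz), `smoothed` (Hz), `n_trials`, `bin_s`.
#' @export
compute_psth <- function(spikes, bin_s = 0.010, kernel_width_s = 0.100) {
  stopifnot(inherits(spikes, "epoched_spikes"))
  if (spikes$n_trials < 1) stop("need >= 1 trial")
  w <- spikes$window
  breaks <- seq(w[1], w[2] + bin_s / 2, by = bin_s)
  centers <- breaks[-length(breaks)] + bin_s / 2
  all_t <- unlist(spikes$trials, use.names = FALSE)
  counts <- if (length(all_t)) {
    tabulate(findInterval(all_t, breaks, rightmost.closed = TRUE),
             nbins = length(centers))
  } else {
    integer(length(centers))
  }
  rate <- counts / (spikes$n_trials * bin_s)
  smoothed <- if (kernel_width_s > 0) {
    gauss_smooth(rate, sd_bins = (kernel_width_s / 2.3548) / bin_s)
  } else {
    rate
  }
  structure(list(times = centers, rate = rate, smoothed = smoothed,
                 n_trials = spikes$n_trials, bin_s = bin_s,
                 window = w),
            class = "psth")
}

# Gaussian smoothing with per-point kernel renormalisation at the edges
# (conserves area for interior bins and avoids edge droop).
gauss_smooth <- function(x, sd_bins) {
  half <- max(1L, ceiling(4 * sd_bins))
  k <- stats::dnorm(-half:half, sd = sd_bins)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  num <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- stats::filter(ones, k, sides = 2)[(half + 1):(half + n)]
  as.numeric(num / den)
}

#' z-score a PSTH against its pre-onset baseline
#'
#' `z(t) = (FR(t) - mean(baseFR)) / sd(baseFR)` on the smoothed rate,
#' where the baseline statistics come from `baseline_window` (relative
#' to stimulus onset; the pre-onset part of the epoch).
#'
#' @param psth A [compute_psth()] result.
#' @param baseline_window Interval relative to onset, seconds.
#' @return List with `times`, `z`, `base_mean`, `base_sd`. A zero
#'   baseline SD raises an error (such units are excluded from z-based
#'   analyses).
#' @export
zscore_psth <- function(psth, baseline_window = c(-0.5, 0)) {
  stopifnot(inherits(psth, "psth"))
  bi <- psth$times >= baseline_window[1] & psth$times <= baseline_window[2]
  if (!any(bi)) stop("baseline window outside the PSTH")
  m <- mean(psth$smoothed[bi])
  s <- stats::sd(psth$smoothed[bi])
  if (!is.finite(s) || s == 0) {
    stop("zero baseline SD; unit excluded from z-score analyses")
  }
  list(times = psth$times, z = (psth$smoothed - m) / s,
       base_mean = m, base_sd = s)
}

#' Visually responsive units by paired Wilcoxon signed-rank test
#'
#' A unit is responsive when its per-trial spike counts in the stimulus
#' window significantly exceed the equal-length baseline window
#' (one-sided paired Wilcoxon signed-rank, alpha level `alpha`): only
#' units that upregulate their firing are kept for the oscillation
#' analyses. Windows are relative to stimulus onset; the defaults
#' correspond to a 0.45-s baseline immediately before onset versus the
#' first 0.45 s of the response.
#'
#' @param spikes An [epoched_spikes()] object (one unit).
#' @param baseline_window,stim_window Equal-length intervals, seconds
#'   relative to onset.
#' @param alpha Significance level.
#' @return List `responsive` (logical; `FALSE` when the test is
#'   undefined, e.g. all-zero differences) and `p_value`.
#' @export
responsive_unit <- function(spikes, baseline_window = c(-0.45, 0),
                            stim_window = c(0, 0.45), alpha = 0.05) {
  stopifnot(inherits(spikes, "epoched_spikes"))
  if (abs(diff(baseline_window) - diff(stim_window)) > 1e-9) {
    stop("baseline and stimulus windows must have equal length")
  }
  nb <- vapply(spikes$trials, function(t)
    sum(t >= baseline_window[1] & t < baseline_window[2]), numeric(1))
  ns <- vapply(spikes$trials, function(t)
    sum(t >= stim_window[1] & t < stim_window[2]), numeric(1))
  d <- ns - nb
  if (all(d == 0)) return(list(responsive = FALSE, p_value = NA_real_))
  p <- stats::wilcox.test(ns, nb, paired = TRUE, alternative = "greater",
                          exact = FALSE, correct = TRUE)$p.value
  list(responsive = is.finite(p) && p < alpha, p_value = p)
}

#' Duration of stimulus-locked oscillatory activity
#'
#' The time of the last strict local maximum of the smoothed z-score
#' trace after stimulus onset whose z exceeds `threshold` (default 1.5).
#' Returns 0 when no post-onset peak qualifies (no detectable
#' oscillatory/persistent activity).
#'
#' @param z A [zscore_psth()] result (or list with `times` and `z`).
#' @param threshold z-score threshold a peak must exceed.
#' @return Time of the last qualifying peak, seconds after onset; 0 if
#'   none.
#' @export
oscillation_duration <- function(z, threshold = 1.5) {
  tt <- z$times; zz <- z$z
  n <- length(zz)
  if (n < 3) return(0)
  is_peak <- c(FALSE, zz[2:(n - 1)] > zz[1:(n - 2)] &
                      zz[2:(n - 1)] > zz[3:n], FALSE)
  qual <- is_peak & zz > threshold & tt > 0
  if (!any(qual)) return(0)
  max(tt[qual])
}

#' Tuning curve: per-level trial responses in a response window
#'
#' Groups trials by stimulus level (direction, spatial frequency, or
#' contrast, inferred from the trial kinds) and computes the per-trial
#' mean firing rate in `response_window` plus per-level mean and SEM.
#'
#' @param spikes An [epoched_spikes()] object aligned to `trials`.
#' @param trials The `trial_table` the spikes were epoched over (same
#'   row order).
#' @param level_var Which stimulus parameter defines the levels:
#'   `"direction_deg"`, `"sf_cpd"`, or `"contrast"`; inferred from the
#'   trial kinds when `NULL`.
#' @param response_window Interval relative to onset, seconds.
#' @return A `tuning_curve`: `levels`, `responses` (list of per-trial Hz
#'   per level), `mean`, `sem`, `level_var`.
#' @export
make_tuning_curve <- function(spikes, trials, level_var = NULL,
                              response_window = c(0.05, 0.5)) {
  stopifnot(inherits(spikes, "epoched_spikes"),
            nrow(trials) == spikes$n_trials)
  if (is.null(level_var)) {
    level_var <- switch(trials$kind[1],
                        drifting_grating = "direction_deg",
                        sf_noise = "sf_cpd",
                        static_grating = "contrast",
                        stop("cannot infer tuning variable from kind '",
                             trials$kind[1], "'"))
  }
  span <- diff(response_window)
  resp <- vapply(spikes$trials, function(t)
    sum(t >= response_window[1] & t < response_window[2]) / span, numeric(1))
  lv <- trials[[level_var]]
  levels <- sort(unique(lv))
  by_level <- lapply(levels, function(l) resp[lv == l])
  structure(list(levels = levels,
                 responses = by_level,
                 mean = vapply(by_level, mean, numeric(1)),
                 sem = vapply(by_level, function(x)
                   stats::sd(x) / sqrt(length(x)), numeric(1)),
                 level_var = level_var,
                 response_window = response_window),
            class = "tuning_curve")
}

#' Orientation selectivity index (resultant vector length)
#'
#' `OSI = sqrt((sum r_k sin 2theta_k)^2 + (sum r_k cos 2theta_k)^2) /
#' sum r_k` with `theta_k` in radians: the length of the mean response
#' vector on the doubled-angle circle. 0 for a flat curve over equally
#' spaced directions, 1 for a response confined to one orientation.
#' Negative mean responses are rectified to 0 (the measure assumes
#' nonnegative weights).
#'
#' @param responses Mean response per direction (Hz), or a
#'   `tuning_curve` over 12 directions.
#' @param directions_deg Directions in degrees (ignored when `responses`
#'   is a `tuning_curve`).
#' @return OSI in `[0, 1]`; `NA` when all responses are zero.
#' @export
osi <- function(responses, directions_deg = NULL) {
  if (inherits(responses, "tuning_curve")) {
    directions_deg <- responses$levels
    responses <- responses$mean
  }
  stopifnot(length(responses) == length(directions_deg))
  r <- pmax(responses, 0)
  if (sum(r) == 0) return(NA_real_)
  th <- directions_deg * pi / 180
  sqrt(sum(r * sin(2 * th))^2 + sum(r * cos(2 * th))^2) / sum(r)
}

#' Fit-error statistic for tuning-curve fits
#'
#' `sum((y_i - f_i)^2) / sum((y_i - mean(y))^2)`: residual sum of squares
#' over the variance of the data. 0 for a perfect fit, 1 for a fit no
#' better than the mean. Downstream analyses include only fits with
#' error < 0.7.
#'
#' @param observed,fitted Equal-length numeric vectors (>= 2 points).
#' @return The error ratio; error if the observed values have zero
#'   variance.
#' @export
fit_error <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) stop("observed values have zero variance; fit error undefined")
  sum((observed - fitted)^2) / denom
}

# Multi-start bounded Levenberg-Marquardt least squares on a prediction
# function `pf(par, x)`. `starts` is a list of named start lists; returns
# list(par, rss) for the convergent start with the lowest residual sum of
# squares, or NULL if none converged. The raw nls.lm optimiser is used so
# over-parameterised models (DoG: 7 parameters on 6 levels) are handled
# by Levenberg-Marquardt damping rather than rejected.
multistart_nls <- function(pf, x, y, starts, lower, upper) {
  best <- NULL
  best_rss <- Inf
  nm <- names(starts[[1]])
  for (st in starts) {
    p0 <- unlist(st)[nm]
    res <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, fn = function(p) y - pf(p, x),
        lower = lower[nm], upper = upper[nm],
        control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (!is.null(res) && res$info %in% 1:4) {
      rss <- sum(res$fvec^2)
      if (rss < best_rss) { best <- res; best_rss <- rss }
    }
  }
  if (is.null(best)) return(NULL)
  list(par = as.list(best$par), rss = best_rss)
}

fit_result <- function(model, params, observed, fitted_vals, converged,
                       derived = list()) {
  fe <- if (converged && stats::var(observed) > 0) {
    fit_error(observed, fitted_vals)
  } else {
    NA_real_
  }
  structure(c(list(model = model, params = params, fit_error = fe,
                   converged = converged, fitted = fitted_vals,
                   observed = observed),
              derived),
            class = "fit_result")
}

#' Fit the double-Gaussian direction tuning model
#'
#' Least-squares fit of [double_gaussian()] to a 12-direction tuning
#' curve, with circular distance for the angle differences. Multi-start
#' (preferred-direction starts at the empirical peak and rotations of
#' it; several width starts) with box bounds (`sigma` in 5-180 deg,
#' amplitudes nonnegative); the lowest-residual convergent fit wins.
#' The derived tuning width is `sigma`.
#'
#' @param curve A `tuning_curve` over the 12 standard directions.
#' @return A `fit_result` with `params` `(R0, Rp, Rn, theta_p, sigma)`,
#'   `fit_error`, `converged`, and `sigma` / `pref_direction` as derived
#'   fields.
#' @export
fit_direction_tuning <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  th <- curve$levels
  y <- curve$mean
  if (length(th) != 12) stop("direction fit expects 12 levels")
  pk <- th[which.max(y)]
  rng <- max(y) - min(y)
  starts <- list()
  for (dth in c(0, -30, 30, 180)) {
    for (sg in c(15, 30, 60)) {
      starts[[length(starts) + 1]] <-
        list(R0 = max(min(y), 0), Rp = max(rng, 1), Rn = max(rng / 3, 0.5),
             theta_p = (pk + dth) %% 360, sigma = sg)
    }
  }
  pf <- function(p, x) double_gaussian(x, p[["R0"]], p[["Rp"]], p[["Rn"]],
                                       p[["theta_p"]], p[["sigma"]])
  fit <- multistart_nls(
    pf, th, y, starts = starts,
    lower = c(R0 = 0, Rp = 0, Rn = 0, theta_p = -360, sigma = 5),
    upper = c(R0 = max(y) + 1e-6, Rp = 3 * max(y) + 1, Rn = 3 * max(y) + 1,
              theta_p = 720, sigma = 180))
  if (is.null(fit)) {
    return(fit_result("double_gaussian", NULL, y, rep(mean(y), length(y)),
                      FALSE))
  }
  p <- fit$par
  p$theta_p <- p$theta_p %% 360
  fitted_vals <- double_gaussian(th, p$R0, p$Rp, p$Rn, p$theta_p, p$sigma)
  fit_result("double_gaussian", p, y, fitted_vals, TRUE,
             derived = list(sigma = p$sigma, pref_direction = p$theta_p))
}

#' Fit the difference-of-Gaussians spatial-frequency tuning model
#'
#' Least-squares DoG fit to a 6-level spatial-frequency tuning curve.
#' Because the stimulus levels are octave-spaced, the model is fitted on
#' a log2-cpd axis by default (`log_axis = FALSE` fits on linear cpd).
#' Derived quantities: preferred SF = empirical argmax level (the level
#' that drives the strongest response), FWHM of the fitted curve above
#' its baseline (in octaves on the log axis), and LSFS = empirical
#' response at the lowest tested SF divided by the response at the
#' preferred SF (low-spatial-frequency suppression; larger = weaker
#' suppression).
#'
#' @param curve A `tuning_curve` over the 6 standard spatial frequencies.
#' @param log_axis Fit on log2(SF) (default) or linear SF.
#' @return A `fit_result` with DoG `params`, `pref_sf`, `fwhm`, `lsfs`.
#' @export
fit_sf_tuning <- function(curve, log_axis = TRUE) {
  stopifnot(inherits(curve, "tuning_curve"))
  sf <- curve$levels
  y <- curve$mean
  if (length(sf) != 6) stop("SF fit expects 6 levels")
  x <- if (log_axis) log2(sf) else sf
  pref_sf <- sf[which.max(y)]
  lsfs <- y[1] / max(y)
  rng <- diff(range(x))
  # 7 parameters exceed the 6 level means, so the fit uses the per-trial
  # responses; with means only, points are duplicated (equal reweighting,
  # same least-squares optimum) to satisfy the solver's m >= n requirement
  x_fit <- rep(x, times = lengths(curve$responses))
  y_fit <- unlist(curve$responses, use.names = FALSE)
  if (length(y_fit) <= 7) {
    x_fit <- rep(x, 2)
    y_fit <- rep(y, 2)
  }
  starts <- list()
  for (mu in x[c(2, 4, 6)]) {
    for (ki in c(0.1, 2)) {
      starts[[length(starts) + 1]] <-
        list(R0 = max(min(y), 0), Ke = max(max(y) - min(y), 1), Ki = ki,
             mu_e = mu, mu_i = min(x), sig_e = rng / 4, sig_i = rng / 3)
    }
  }
  pf <- function(p, xx) dog_model(xx, p[["R0"]], p[["Ke"]], p[["Ki"]],
                                  p[["mu_e"]], p[["mu_i"]],
                                  p[["sig_e"]], p[["sig_i"]])
  fit <- multistart_nls(
    pf, x_fit, y_fit, starts = starts,
    lower = c(R0 = 0, Ke = 0, Ki = -3 * max(y) - 1, mu_e = min(x) - rng,
              mu_i = min(x) - rng, sig_e = 0.05, sig_i = 0.05),
    upper = c(R0 = max(y) + 1e-6, Ke = 5 * max(y) + 1, Ki = 5 * max(y) + 1,
              mu_e = max(x) + rng, mu_i = max(x) + rng,
              sig_e = 3 * rng, sig_i = 3 * rng))
  if (is.null(fit)) {
    return(fit_result("dog", NULL, y, rep(mean(y), length(y)), FALSE,
                      derived = list(pref_sf = pref_sf, lsfs = lsfs,
                                     fwhm = NA_real_)))
  }
  p <- fit$par
  fitted_vals <- dog_model(x, p$R0, p$Ke, p$Ki, p$mu_e, p$mu_i,
                           p$sig_e, p$sig_i)
  grid <- seq(min(x) - rng / 2, max(x) + rng / 2, length.out = 600)
  fv <- dog_model(grid, p$R0, p$Ke, p$Ki, p$mu_e, p$mu_i, p$sig_e, p$sig_i)
  fwhm <- curve_fwhm(grid, fv, baseline = p$R0)
  fit_result("dog", p, y, fitted_vals, TRUE,
             derived = list(pref_sf = pref_sf, lsfs = lsfs, fwhm = fwhm,
                            log_axis = log_axis))
}

# Full width at half maximum of a curve above `baseline`, on the grid's
# axis; NA when the half-maximum is never crossed on both sides.
curve_fwhm <- function(grid, vals, baseline = min(vals)) {
  pk <- which.max(vals)
  half <- baseline + (vals[pk] - baseline) / 2
  above <- vals >= half
  if (!above[pk]) return(NA_real_)
  lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < length(vals) && above[hi + 1]) hi <- hi + 1
  if (lo == 1 || hi == length(vals)) return(grid[hi] - grid[lo])
  grid[hi] - grid[lo]
}

#' Fit the hyperbolic-ratio contrast response model
#'
#' Least-squares fit of [hyperbolic_ratio()] to a 5-level contrast
#' response curve, multi-start with box bounds (`c50` in `[0.01, 1]`,
#' `n` in `[0.5, 6]`). Exposes the semisaturation contrast `c50` and
#' exponent `n`.
#'
#' @param curve A `tuning_curve` over the 5 standard contrasts.
#' @return A `fit_result` with `params` `(R0, Rmax, n, c50)` and `c50`,
#'   `n_exp` derived fields.
#' @export
fit_contrast <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  cc <- curve$levels
  y <- curve$mean
  if (length(cc) != 5) stop("contrast fit expects 5 levels")
  rng <- max(y) - min(y)
  starts <- list()
  for (c50s in c(0.1, 0.3, 0.6)) {
    for (ns in c(1, 2, 4)) {
      starts[[length(starts) + 1]] <-
        list(R0 = max(min(y), 0), Rmax = max(rng, 1), n = ns, c50 = c50s)
    }
  }
  pf <- function(p, x) hyperbolic_ratio(x, p[["R0"]], p[["Rmax"]],
                                        p[["n"]], p[["c50"]])
  fit <- multistart_nls(
    pf, cc, y, starts = starts,
    lower = c(R0 = 0, Rmax = 0, n = 0.5, c50 = 0.01),
    upper = c(R0 = max(y) + 1e-6, Rmax = 5 * max(y) + 1, n = 6, c50 = 1))
  if (is.null(fit)) {
    return(fit_result("hyperbolic_ratio", NULL, y, rep(mean(y), length(y)),
                      FALSE))
  }
  p <- fit$par
  fitted_vals <- hyperbolic_ratio(cc, p$R0, p$Rmax, p$n, p$c50)
  fit_result("hyperbolic_ratio", p, y, fitted_vals, TRUE,
             derived = list(c50 = p$c50, n_exp = p$n))
}

#' Histogram of preferred directions and the cardinal-bias statistic
#'
#' Counts units preferring each direction level (preferred = empirical
#' argmax of the tuning curve) and the fraction preferring a cardinal
#' direction (0, 90, 180, 270 deg); under uniform preferences that
#' fraction is 4/12.
#'
#' @param curves List of 12-direction `tuning_curve`s (or a numeric
#'   vector of preferred directions in degrees).
#' @param levels Direction levels, degrees.
#' @return List `counts` (named per level), `cardinal_fraction`.
#' @export
preferred_orientation_histogram <- function(curves,
                                            levels = tuning_levels("orientation")) {
  prefs <- if (is.numeric(curves)) {
    curves
  } else {
    vapply(curves, function(cv) cv$levels[which.max(cv$mean)], numeric(1))
  }
  counts <- vapply(levels, function(l) sum(prefs == l), numeric(1))
  names(counts) <- levels
  cardinal <- sum(prefs %% 360 %in% c(0, 90, 180, 270)) / length(prefs)
  list(counts = counts, cardinal_fraction = cardinal)
}
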