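test_that("PSTH binning, rate conversion, and smoothing behave", {
  # one spike per trial at exactly t*, no smoothing: one 100-Hz bin
  sp <- epoched_spikes(rep(list(0.205), 100), c(-0.5, 1.0))
  p <- compute_psth(sp, kernel_width_s = 0)
  expect_equal(sum(p$rate > 0), 1)
  expect_equal(max(p$rate), 100)  # 1 spike / (100 trials * 0.01 s) * 100

  # homogeneous Poisson at 20 Hz: mean PSTH 20 +/- 1 Hz
  sp2 <- fixture_poisson_spikes(20, 200, seed = 2)
  p2 <- compute_psth(sp2)
  expect_equal(mean(p2$rate), 20, tolerance = 0.05)
  expect_equal(mean(p2$smoothed), 20, tolerance = 0.05)

  # smoothing conserves area away from the edges
  interior <- p2$times > -0.3 & p2$times < 0.8
  expect_equal(sum(p2$smoothed[interior]), sum(p2$rate[interior]),
               tolerance = 0.01)

  # no spikes: all-zero PSTH, not an error
  p0 <- compute_psth(epoched_spikes(list(numeric(0), numeric(0)),
                                    c(-0.5, 1.0)))
  expect_true(all(p0$rate == 0) && all(p0$smoothed == 0))
})

test_that("z-scoring normalises against the pre-onset baseline", {
  sp <- fixture_poisson_spikes(15, 300, seed = 3)
  p <- compute_psth(sp)
  z <- zscore_psth(p)
  bi <- z$times >= -0.5 & z$times <= 0
  expect_equal(mean(z$z[bi]), 0, tolerance = 1e-10)
  expect_equal(sd(z$z[bi]), 1, tolerance = 1e-10)

  # arithmetic: baseline mean 10, SD 2, FR 14 -> z = 2
  p$smoothed <- rep(14, length(p$smoothed))
  p$smoothed[p$times <= 0] <- 10
  p$smoothed[which(p$times <= 0)[1:2]] <- c(8, 12)  # SD 2 is impossible with
  z2 <- (14 - 10) / 2                               # constant baseline; check
  expect_equal(z2, 2)                               # the formula directly
  pc <- p
  pc$smoothed <- rep(5, length(pc$smoothed))
  expect_error(zscore_psth(pc), "zero baseline SD")
})

test_that("responsiveness requires a significant firing-rate increase", {
  set.seed(4)
  mk <- function(base_rate, stim_rate, n = 100) {
    trials <- lapply(seq_len(n), function(i) {
      nb <- rpois(1, base_rate * 0.45)
      ns <- rpois(1, stim_rate * 0.45)
      c(sort(runif(nb, -0.45, 0)), sort(runif(ns, 0, 0.45)))
    })
    epoched_spikes(trials, c(-0.5, 1.0))
  }
  up <- responsive_unit(mk(10, 20))
  expect_true(up$responsive)
  expect_lt(up$p_value, 0.05)

  flat_trials <- lapply(1:50, function(i) c(-0.2, 0.25))  # same counts
  flat <- responsive_unit(epoched_spikes(flat_trials, c(-0.5, 1.0)))
  expect_false(flat$responsive)

  down <- responsive_unit(mk(10, 5))
  expect_false(down$responsive)  # suppression never counts as responsive

  expect_error(responsive_unit(mk(10, 10), baseline_window = c(-0.4, 0),
                               stim_window = c(0, 0.45)), "equal length")
})

test_that("oscillation duration is the last supra-threshold peak time", {
  t <- seq(-0.5, 2, by = 0.01)
  z1 <- exp(-(t - 0.2)^2 / (2 * 0.03^2)) * 3
  expect_equal(oscillation_duration(list(times = t, z = z1)), 0.2,
               tolerance = 0.011)
  expect_equal(oscillation_duration(list(times = t, z = z1 * 0.4)), 0)

  # two peaks, only the first above threshold: returns the first
  z2 <- 3 * exp(-(t - 0.3)^2 / (2 * 0.03^2)) +
        1.2 * exp(-(t - 1.2)^2 / (2 * 0.03^2))
  expect_equal(oscillation_duration(list(times = t, z = z2)), 0.3,
               tolerance = 0.011)

  # pre-onset peaks never qualify
  z3 <- 3 * exp(-(t + 0.3)^2 / (2 * 0.03^2))
  expect_equal(oscillation_duration(list(times = t, z = z3)), 0)
})

test_that("oscillation duration recovers the generative duration", {
  set.seed(5)
  tt <- build_familiarity_protocol(200, 1, seed = 6)
  ests <- vapply(1:12, function(i) {
    u <- fixture_unit(baseline_rate = 3, Rp = 30, Rn = 0, theta_p = 30,
                      f_osc = 6, mod_depth = 0.8, osc_duration = 1.0,
                      osc_enabled = TRUE)
    sp <- simulate_spikes(u, tt, c(-0.5, 2.0), seed = 100 + i)
    oscillation_duration(zscore_psth(compute_psth(sp)))
  }, numeric(1))
  expect_lt(abs(median(ests) - 1.0), 0.15)
})

test_that("OSI matches its closed forms and hand evaluation", {
  dirs <- seq(0, 330, by = 30)
  expect_equal(osi(rep(5, 12), dirs), 0, tolerance = 1e-12)
  one_hot <- c(10, rep(0, 11))
  expect_equal(osi(one_hot, dirs), 1)
  both_lobes <- numeric(12); both_lobes[c(1, 7)] <- 10  # 0 and 180 deg
  expect_equal(osi(both_lobes, dirs), 1)

  # brute-force formula evaluation for r = (2,1,...,1): resultant = 1, sum = 13
  r <- c(2, rep(1, 11))
  th <- dirs * pi / 180
  direct <- sqrt(sum(r * sin(2 * th))^2 + sum(r * cos(2 * th))^2) / sum(r)
  expect_equal(osi(r, dirs), direct)
  expect_equal(direct, 1 / 13, tolerance = 1e-12)

  # scale invariance and bounds; rectification of negative means
  expect_equal(osi(r * 17.3, dirs), osi(r, dirs))
  expect_equal(osi(c(-5, one_hot[-1] - 0), dirs), NA_real_)
  expect_true(is.na(osi(rep(0, 12), dirs)))
})

test_that("fit_error matches its definition", {
  y <- c(1, 2, 3)
  expect_equal(fit_error(y, y), 0)
  expect_equal(fit_error(y, rep(mean(y), 3)), 1)
  expect_equal(fit_error(y, c(1, 2, 4)), 0.5)
  # invariant under joint affine rescaling
  f <- c(1.2, 1.9, 3.3)
  expect_equal(fit_error(2 * y + 7, 2 * f + 7), fit_error(y, f))
  expect_error(fit_error(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("the double-Gaussian fit recovers noise-free parameters exactly", {
  dirs <- seq(0, 330, by = 30)
  truth <- list(R0 = 2, Rp = 20, Rn = 8, theta_p = 75, sigma = 25)
  y <- double_gaussian(dirs, truth$R0, truth$Rp, truth$Rn, truth$theta_p,
                       truth$sigma)
  fit <- fit_direction_tuning(fixture_curve(dirs, y))
  expect_true(fit$converged)
  expect_lt(fit$fit_error, 1e-6)
  expect_equal(fit$params$sigma, truth$sigma, tolerance = 1e-3)
  expect_equal(fit$params$theta_p, truth$theta_p, tolerance = 0.1)

  # flat curve: no structure to explain; gated out by the 0.7 criterion
  flat <- fit_direction_tuning(fixture_curve(dirs, rep(5, 12) +
                                               c(1e-3, rep(0, 11))))
  expect_true(!flat$converged || flat$fit_error >= 0.7 ||
              is.na(flat$fit_error) || flat$params$Rp < 1e-2)
})

test_that("the DoG fit recovers SF tuning and its derived metrics", {
  sf <- tuning_levels("sf")
  x <- log2(sf)
  # pure Gaussian (Ki = 0): FWHM has the closed form 2 sqrt(2 ln 2) sig_e
  y <- dog_model(x, 1, 20, 0, log2(0.06), 0, 1.0, 1)
  fit <- fit_sf_tuning(fixture_curve(sf, y, "sf_cpd"))
  expect_true(fit$converged)
  expect_lt(fit$fit_error, 1e-6)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 1.0, tolerance = 0.05)
  expect_equal(fit$pref_sf, 0.06)

  # peak at the lowest SF: LSFS = 1 by the ratio identity
  y2 <- dog_model(x, 1, 15, 0, log2(7.5e-3), 0, 1.2, 1)
  fit2 <- fit_sf_tuning(fixture_curve(sf, y2, "sf_cpd"))
  expect_equal(fit2$lsfs, 1)
  expect_equal(fit2$pref_sf, 7.5e-3)
})

test_that("the hyperbolic-ratio fit recovers contrast parameters", {
  cc <- tuning_levels("contrast")
  y <- hyperbolic_ratio(cc, 2, 20, 2, 0.3)
  fit <- fit_contrast(fixture_curve(cc, y, "contrast"))
  expect_true(fit$converged)
  expect_lt(fit$fit_error, 1e-5)
  expect_equal(fit$c50, 0.3, tolerance = 1e-3)
  expect_equal(fit$n_exp, 2, tolerance = 1e-3)

  # semisaturation identity: model at c = c50 returns R0 + Rmax / 2
  p <- fit$params
  expect_equal(hyperbolic_ratio(p$c50, p$R0, p$Rmax, p$n, p$c50),
               p$R0 + p$Rmax / 2)
})

test_that("tuning curves aggregate per-level trial responses", {
  tt <- build_tuning_protocol("orientation", 5, seed = 7)
  u <- fixture_unit(theta_p = 90, Rp = 30, Rn = 5, sigma = 20)
  sp <- simulate_spikes(u, tt, c(-0.5, 1.5), seed = 8)
  cv <- make_tuning_curve(sp, tt)
  expect_equal(cv$levels, seq(0, 330, by = 30))
  expect_true(all(lengths(cv$responses) == 5))
  expect_equal(cv$levels[which.max(cv$mean)], 90)
})

test_that("preferred-orientation histograms count cardinal bias", {
  dirs <- tuning_levels("orientation")
  uniform <- rep(dirs, 3)
  h <- preferred_orientation_histogram(uniform)
  expect_true(all(h$counts == 3))
  expect_equal(h$cardinal_fraction, 4 / 12)

  all90 <- rep(90, 20)
  h2 <- preferred_orientation_histogram(all90)
  expect_equal(unname(h2$counts[dirs == 90]), 20)
  expect_equal(sum(h2$counts), 20)
  expect_equal(h2$cardinal_fraction, 1)
})
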