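rms <- function(x) sqrt(mean(x^2))

test_that("preprocessing preserves the passband, notches 60 Hz, decimates", {
  fs <- 3000
  t <- seq(0, 10, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  out <- preprocess_lfp(x10, fs)
  expect_equal(out$fs_hz, 1000)
  expect_equal(nrow(out$data), ceiling(length(t) / 3))
  mid <- 2000:8000  # away from filter edges
  expect_equal(rms(out$data[mid, 1]), rms(x10) , tolerance = 0.01)

  x60 <- sin(2 * pi * 60 * t)
  out60 <- preprocess_lfp(x60, fs)
  expect_lt(rms(out60$data[mid, 1]), 0.1 * rms(x60))

  # zero net group delay: a slow transient stays put
  pulse <- exp(-(t - 5)^2 / (2 * 0.05^2))
  outp <- preprocess_lfp(pulse, fs)
  expect_equal(which.max(outp$data[, 1]) / 1000, 5, tolerance = 0.002)

  expect_error(preprocess_lfp(x10, 500), ">= 1 kHz")
})

test_that("layer-IV channel selection finds the strongest early sink", {
  ep <- fixture_lfp_epochs(n_trials = 1, layer4 = 6, noise_sd = 0)
  expect_equal(find_layer4_channel(ep), 6)

  # noisy replicates: noise SD = 20% of deflection amplitude, 100 trials
  set.seed(42)
  hits <- vapply(1:30, function(i) {
    ep <- fixture_lfp_epochs(n_trials = 100, layer4 = 6, noise_sd = 20,
                             window = c(-0.5, 0.3))
    find_layer4_channel(ep) == 6
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  ep0 <- fixture_lfp_epochs(n_trials = 2, deflect_amp = 0, noise_sd = 0)
  expect_error(find_layer4_channel(ep0), "indeterminate")
})

test_that("the Morlet family is log-spaced with log-spaced cycles", {
  two <- wavelet_family(n = 2)
  expect_equal(two$freqs, c(2, 80))
  expect_equal(two$cycles, c(3, 10))

  fam <- wavelet_family()
  expect_length(fam$freqs, 40)
  ratios <- fam$freqs[-1] / fam$freqs[-40]
  expect_equal(ratios, rep((80 / 2)^(1 / 39), 39), tolerance = 1e-10)
  expect_true(all(diff(fam$freqs) > 0))

  # unit energy and spectral peak at the centre frequency (within one bin)
  for (i in c(1, 10, 25, 40)) {
    w <- fam$wavelets[[i]]
    expect_equal(sum(Mod(w)^2), 1, tolerance = 1e-8)
    n <- 2^14
    spec <- Mod(stats::fft(c(w, rep(0, n - length(w)))))
    f_axis <- (seq_len(n) - 1) * fam$fs_hz / n
    pk <- f_axis[which.max(spec[1:(n / 2)])]
    expect_lt(abs(pk - fam$freqs[i]), fam$fs_hz / n + 1e-9)
  }
})

test_that("tf power is ~0 dB for stationary input and finds injected bursts", {
  # stationary white noise: induced-power map approximately flat (0 dB)
  set.seed(1)
  nt <- 5
  win <- c(-2, 8)
  times <- seq(win[1], win[2], by = 1e-3)
  ep <- structure(list(
    data = array(stats::rnorm(nt * length(times)),
                 dim = c(nt, 1, length(times))),
    times = times, fs_hz = 1000, window = win, n_trials = nt,
    n_channels = 1), class = "lfp_epochs")
  fam12 <- wavelet_family(n = 12)
  tm <- tf_power(ep, 1, baseline_window = c(-1.5, -0.5), family = fam12,
                 evoked = FALSE)
  interior <- tm$times > -1 & tm$times < 7
  expect_lt(max(abs(rowMeans(tm$values[, interior]))), 1.5)

  # onset-locked 6-Hz burst over pink-noise background: theta wins
  tt <- build_familiarity_protocol(20, 1, seed = 1,
                                   condition = "post_familiar")
  lfp <- simulate_lfp(tt, n_channels = 2, layer4_channel = 1,
                      condition = "post_familiar", seed = 4,
                      theta_f = 6, theta_amp = 40)
  ep2 <- epoch_lfp(lfp, tt$onset_s, window = c(-0.5, 1.5))
  tm2 <- tf_power(ep2, 1)
  post <- tm2$times > 0 & tm2$times < 1
  band_prof <- rowMeans(tm2$values[, post])
  peak_f <- tm2$freqs[which.max(band_prof)]
  expect_gte(peak_f, 4); expect_lte(peak_f, 8)
  bands <- vapply(names(lfp_bands()), function(b) band_power(tm2, b),
                  numeric(1))
  expect_equal(names(which.max(bands)), "theta")

  # dB arithmetic: doubling a stationary tone's amplitude post-onset ~ +6 dB
  tone <- sin(2 * pi * 6 * times)
  step <- ifelse(times > 0, 2, 1) * tone + 1e-3 * stats::rnorm(length(times))
  ep3 <- structure(list(
    data = array(rep(tone, each = 1), dim = c(1, 1, length(times))),
    times = times, fs_hz = 1000, window = win, n_trials = 1,
    n_channels = 1), class = "lfp_epochs")
  ep3$data[1, 1, ] <- step
  tm3 <- tf_power(ep3, 1, baseline_window = c(-1.8, -0.8), family = fam12)
  i6 <- which.min(abs(tm3$freqs - 6))
  late <- tm3$times > 1 & tm3$times < 6
  expect_equal(mean(tm3$values[i6, late]), 20 * log10(2), tolerance = 0.5)

  # gain invariance: scaling the whole recording leaves the dB map unchanged
  ep4 <- ep2; ep4$data <- ep4$data * 7.3
  tm4 <- tf_power(ep4, 1)
  expect_equal(tm4$values, tm2$values, tolerance = 1e-8)

  expect_error(tf_power(ep2, 1, baseline_window = c(0.1, 0.4)), "pre-onset")
})

test_that("band_power averages the right selection", {
  fam <- wavelet_family(n = 10)
  flat <- v1tune:::tf_map(fam$freqs, seq(-0.5, 1, by = 0.01),
                          matrix(3, 10, 151), "power_db")
  for (b in names(lfp_bands())) expect_equal(band_power(flat, b), 3)
  expect_error(band_power(flat, c(100, 120)), "empty")
})

test_that("ITPC is 1 for identical trials, 0 for balanced phases, ~1/sqrt(N) for noise", {
  fam <- wavelet_family(n = 10)
  base <- fixture_lfp_epochs(n_trials = 1, n_channels = 1, layer4 = 1,
                             deflect_amp = 0, window = c(-0.5, 1.0))
  tt <- base$times

  ident <- base
  trace <- sin(2 * pi * 6 * tt) + 0.3 * sin(2 * pi * 20 * tt)
  ident$data <- array(rep(trace, each = 8), dim = c(8, 1, length(tt)))
  ident$n_trials <- 8
  m1 <- itpc(ident, 1, family = fam)
  expect_true(all(m1$values > 1 - 1e-6))
  expect_true(all(m1$freqs <= 40))

  # N trials with phases evenly spaced on the circle cancel exactly
  n <- 8
  spread <- base
  spread$data <- array(0, dim = c(n, 1, length(tt)))
  for (k in seq_len(n)) {
    spread$data[k, 1, ] <- sin(2 * pi * 6 * tt + 2 * pi * (k - 1) / n)
  }
  spread$n_trials <- n
  m0 <- itpc(spread, 1, family = fam)
  i6 <- which.min(abs(m0$freqs - 6))
  mid <- m0$times > -0.2 & m0$times < 0.7
  expect_lt(max(m0$values[i6, mid]), 0.02)

  # i.i.d. random-phase trials: mean ITPC near sqrt(pi)/2/sqrt(N), < 2/sqrt(N)
  set.seed(3)
  n <- 100
  rnd <- base
  rnd$data <- array(stats::rnorm(n * length(tt)), dim = c(n, 1, length(tt)))
  rnd$n_trials <- n
  mr <- itpc(rnd, 1, family = fam)
  expect_lt(mean(mr$values), 2 / sqrt(n))
  expect_equal(mean(mr$values), sqrt(pi) / 2 / sqrt(n), tolerance = 0.25)

  # common phase offset leaves ITPC unchanged
  shifted <- spread
  for (k in seq_len(8)) {
    shifted$data[k, 1, ] <- sin(2 * pi * 6 * tt + 2 * pi * (k - 1) / 8 + 1.1)
  }
  ms <- itpc(shifted, 1, family = fam)
  expect_equal(ms$values[i6, mid], m0$values[i6, mid], tolerance = 1e-6)

  expect_true(all(m1$values >= 0 & m1$values <= 1))
  one <- base; one$n_trials <- 1
  expect_error(itpc(one, 1), "2 trials")
})

test_that("simulated LFP carries the depth profile, theta burst, and line noise", {
  tt <- build_familiarity_protocol(10, 1, seed = 1,
                                   condition = "post_familiar")
  lfp <- simulate_lfp(tt, n_channels = 8, layer4_channel = 3,
                      condition = "post_familiar", seed = 2, noise_sd = 0)
  ep <- epoch_lfp(lfp, tt$onset_s, window = c(-0.5, 1.5))
  expect_equal(find_layer4_channel(ep), 3)

  m <- itpc(ep, 3, family = wavelet_family(n = 10))
  i6 <- which.min(abs(m$freqs - 6))
  sel <- m$times > 0 & m$times <= 0.5
  expect_gt(mean(m$values[i6, sel]), 0.9)  # trial-consistent theta phase

  # 60-Hz contaminant: visible pre-notch, attenuated >= 20 dB post-notch
  noisy <- simulate_lfp(tt, n_channels = 2, layer4_channel = 1,
                        seed = 3, noise_sd = 1, line_amp = 50)
  spec_at <- function(x, f, fs) {
    n <- length(x)
    Mod(stats::fft(x))[round(f * n / fs) + 1]
  }
  pre <- spec_at(noisy$data[, 1], 60, 1000)
  base_pre <- spec_at(noisy$data[, 1], 45, 1000)
  expect_gt(pre / base_pre, 10)
  post <- preprocess_lfp(noisy, 1000)
  expect_lt(spec_at(post$data[, 1], 60, 1000), pre * 10^(-20 / 20))

  expect_error(simulate_lfp(tt, fs_hz = 100), "200")
  expect_error(simulate_lfp(tt, n_channels = 4, layer4_channel = 9),
               "channel")
})
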