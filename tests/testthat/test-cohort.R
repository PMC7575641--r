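zero_dispersion_config <- function(n_units = 5) {
  cfg <- default_cohort_config(n_units = n_units)
  for (g in names(cfg$priors)) {
    for (cond in names(cfg$priors[[g]])) {
      p <- cfg$priors[[g]][[cond]]
      for (nm in names(p)) {
        if (is.numeric(p[[nm]]) && length(p[[nm]]) == 2) p[[nm]][2] <- 0
      }
      p$cardinal_bias <- 1
      cfg$priors[[g]][[cond]] <- p
    }
  }
  cfg
}

test_that("unit sampling follows the priors and encodes the KO effects", {
  cfg0 <- zero_dispersion_config()
  u0 <- sample_units(cfg0, "WT", "pre", seed = 1)
  expect_equal(nrow(u0), 5)
  expect_true(all(u0$sigma == u0$sigma[1]))     # zero dispersion: identical
  expect_true(all(u0$baseline_rate == cfg0$priors$WT$pre$baseline_rate[1]))

  cfg <- default_cohort_config(n_units = 400)
  u <- sample_units(cfg, "WT", "pre", seed = 2)
  prior <- cfg$priors$WT$pre$sigma
  se <- prior[2] / sqrt(400)
  expect_lt(abs(mean(u$sigma) - prior[1]), 3.5 * se)

  ko <- sample_units(cfg, "KO", "post_familiar", seed = 3)
  wt <- sample_units(cfg, "WT", "post_familiar", seed = 3)
  expect_gt(mean(ko$osc_duration), mean(wt$osc_duration))
  expect_gt(mean(ko$sigma), mean(wt$sigma))
  expect_gt(mean(ko$lsfs_target), mean(wt$lsfs_target))

  expect_identical(sample_units(cfg, "KO", "pre", seed = 5),
                   sample_units(cfg, "KO", "pre", seed = 5))
  expect_error(sample_units(cfg, "XX", "pre"), "genotype")
  expect_error(sample_units(cfg, "WT", "mid"), "condition")
})

test_that("untuned, unmodulated units produce homogeneous Poisson counts", {
  unit <- fixture_unit(baseline_rate = 20, Rp = 0, Rn = 0, Ke = 0, Rmax = 0,
                       novel_amp = 0)
  tt <- build_familiarity_protocol(200, 1, seed = 1)
  sp <- simulate_spikes(unit, tt, epoch_window = c(-0.5, 1.5), seed = 4)
  counts <- lengths(sp$trials)
  expect_equal(mean(counts), 20 * 2, tolerance = 0.1)   # rate * window
  fano <- var(counts) / mean(counts)
  expect_gt(fano, 0.7)
  expect_lt(fano, 1.3)
  expect_true(all(unlist(sp$trials) >= -0.5 & unlist(sp$trials) <= 1.5))
})

test_that("the generative rate honors the tuning models", {
  unit <- fixture_unit(theta_p = 90, Rp = 25, Rn = 8, sigma = 25)
  stim <- data.frame(kind = "drifting_grating", direction_deg = 90,
                     sf_cpd = 0.04, tf_hz = 2, contrast = 1,
                     duration_s = 0.5)
  expect_equal(v1tune:::unit_tuned_response(unit, stim), 25)  # Rp at theta_p
  stim$direction_deg <- 270
  expect_equal(v1tune:::unit_tuned_response(unit, stim), 8)   # Rn at null

  # counts scale linearly with rate over a 10x range
  tt <- build_familiarity_protocol(150, 1, seed = 2)
  rates <- c(4, 8, 16, 40)
  means <- vapply(rates, function(r) {
    u <- fixture_unit(baseline_rate = r, Rp = 0, Rn = 0, Ke = 0, Rmax = 0,
                      novel_amp = 0)
    mean(lengths(simulate_spikes(u, tt, c(-0.5, 1.5), seed = 7)$trials))
  }, numeric(1))
  slope <- coef(lm(means ~ rates))[["rates"]]
  expect_equal(slope, 2.0, tolerance = 0.05)  # window length = 2 s
})

test_that("oscillating units show theta-spaced PSTH peaks", {
  unit <- fixture_unit(baseline_rate = 2, Rp = 30, Rn = 0, theta_p = 30,
                       f_osc = 6, mod_depth = 0.8, osc_duration = 1.0,
                       osc_enabled = TRUE)
  tt <- build_familiarity_protocol(200, 1, seed = 3)
  sp <- simulate_spikes(unit, tt, c(-0.5, 2.0), seed = 5)
  psth <- compute_psth(sp)
  post <- psth$times > 0.05 & psth$times < 1.05
  r <- psth$smoothed[post]
  pk <- which(diff(sign(diff(r))) == -2) + 1
  expect_gte(length(pk), 5)
  spacing <- diff(psth$times[post][pk])
  expect_equal(median(spacing), 1 / 6, tolerance = 0.03)
})

test_that("cohort recordings round-trip byte-identically through disk", {
  cfg <- default_cohort_config(n_units = 2)
  cohort <- simulate_cohort(cfg, seed = 9, n_familiar = 5,
                            orientation_repeats = 1, sf_repeats = 1,
                            contrast_repeats = 1,
                            conditions = c("pre", "post_familiar"),
                            genotypes = c("WT", "KO"),
                            with_lfp = TRUE, n_channels = 4,
                            layer4_channel = 2)
  root <- withr::local_tempdir()
  d1 <- file.path(root, "w1"); d2 <- file.path(root, "w2")
  write_cohort(cohort, d1)
  dirs <- list.dirs(d1, recursive = FALSE)
  expect_length(dirs, 4)  # 2 genotypes x 2 conditions

  rec <- read_recording(dirs[1])
  expect_length(rec$spike_clusters, length(rec$spike_samples))
  expect_true(all(rec$cluster_group$group == "good"))

  # write -> read -> write is byte-identical for every file
  base <- basename(dirs[1])
  rec_obj <- cohort$recordings[[base]]
  write_recording(file.path(d2, base), rec_obj$units,
                  v1tune:::flatten_recording(rec_obj)$spikes,
                  rec$lfp, rec$trials)
  for (f in list.files(dirs[1])) {
    if (f == "ground_truth.tsv") next  # re-read lfp/trials, not truth
    expect_identical(readBin(file.path(dirs[1], f), "raw",
                             file.size(file.path(dirs[1], f))),
                     readBin(file.path(d2, base, f),
                             "raw", file.size(file.path(d2, base, f))),
                     label = paste("bytes of", f))
  }

  # re-epoched cluster spikes match the simulated epochs (to sample clock)
  flat <- v1tune:::flatten_recording(rec_obj)
  ep <- epoch_cluster(rec, 1, epoch_window = cfg$epoch_window)
  orig <- unlist(flat$spikes[[1]]$trials)
  back <- unlist(ep$trials)
  expect_equal(length(back), length(orig))
  expect_equal(sort(back), sort(orig), tolerance = 1 / 30000 + 1e-9)
})
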