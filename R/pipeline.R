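# Derived sub-seed, kept inside 32-bit integer range.
sub_seed <- function(seed, i, j = 0) {
  as.integer((as.numeric(seed) * 31 + i * 7919 + j * 104729) %% 2147483629)
}

#' Simulate a full synthetic cohort
#'
#' One recording per genotype x condition. Each recording holds a
#' ground-truth unit table drawn from the config priors, a
#' familiarity-block protocol (the familiar grating, or the checkerboard
#' for `post_novel`), the three tuning protocols, and inhomogeneous-
#' Poisson spike trains for every unit over every protocol. Optionally a
#' multichannel LFP is simulated over the familiarity block. The default
#' repeat counts keep 4-fold cross-validation test folds at or above 30
#' trials for every protocol.
#'
#' @param config A [default_cohort_config()].
#' @param seed Integer master seed; all draws derive from it.
#' @param n_familiar Presentations in the familiarity test block.
#' @param orientation_repeats,sf_repeats,contrast_repeats Repeats per
#'   level in the tuning protocols.
#' @param conditions Conditions to simulate (subset of the config's).
#' @param genotypes Genotypes to simulate (subset of the config's).
#' @param with_lfp Simulate the familiarity-block LFP.
#' @param n_channels,layer4_channel LFP probe geometry when `with_lfp`.
#' @param n_lfp_trials LFP is simulated over the first `n_lfp_trials`
#'   presentations of the familiarity block (continuous multichannel
#'   traces are by far the largest object in a cohort; the phase-locking
#'   and band-power analyses stabilise within a 20-trial block).
#' @return A `cohort`: list with `config`, `seed`, and `recordings`
#'   (each with `genotype`, `condition`, `units`, `protocols`,
#'   `spikes[[protocol]][[unit]]`, optional `lfp`).
#' @export
simulate_cohort <- function(config = default_cohort_config(), seed = 1L,
                            n_familiar = 20,
                            orientation_repeats = 12,
                            sf_repeats = 20,
                            contrast_repeats = 24,
                            conditions = config$conditions,
                            genotypes = config$genotypes,
                            with_lfp = FALSE,
                            n_channels = 32, layer4_channel = 12,
                            n_lfp_trials = 20) {
  recordings <- list()
  ri <- 0L
  for (g in genotypes) {
    for (cond in conditions) {
      ri <- ri + 1L
      units <- sample_units(config, g, cond, seed = sub_seed(seed, ri))
      fam_spec <- if (cond == "post_novel") {
        stimulus_spec("checkerboard", duration_s = 0.5)
      } else {
        stimulus_spec("drifting_grating", direction_deg = 30, sf_cpd = 0.04,
                      tf_hz = 2, contrast = 1, duration_s = 0.4)
      }
      protocols <- list(
        familiar = build_familiarity_protocol(
          n_familiar, 1, spec = fam_spec, condition = cond,
          seed = sub_seed(seed, ri, 1)),
        orientation = build_tuning_protocol(
          "orientation", orientation_repeats, condition = cond,
          seed = sub_seed(seed, ri, 2)),
        sf = build_tuning_protocol(
          "sf", sf_repeats, condition = cond, seed = sub_seed(seed, ri, 3)),
        contrast = build_tuning_protocol(
          "contrast", contrast_repeats, condition = cond,
          seed = sub_seed(seed, ri, 4)))
      spikes <- lapply(seq_along(protocols), function(pi) {
        tt <- protocols[[pi]]
        lapply(seq_len(nrow(units)), function(ui) {
          simulate_spikes(units[ui, ], tt, config$epoch_window,
                          seed = sub_seed(seed, ri, 10 + pi * 100 + ui))
        })
      })
      names(spikes) <- names(protocols)
      rec <- list(genotype = g, condition = cond, units = units,
                  protocols = protocols, spikes = spikes)
      if (with_lfp) {
        lfp_trials <- protocols$familiar[
          seq_len(min(n_lfp_trials, nrow(protocols$familiar))), ,
          drop = FALSE]
        rec$lfp <- simulate_lfp(lfp_trials,
                                n_channels = n_channels,
                                layer4_channel = layer4_channel,
                                condition = cond,
                                seed = sub_seed(seed, ri, 5))
      }
      recordings[[paste0(g, "_", cond)]] <- rec
    }
  }
  structure(list(config = config, seed = seed, recordings = recordings),
            class = "cohort")
}

#' Per-unit analysis of one recording
#'
#' Runs the single-unit pipeline over every unit of a simulated (or
#' re-read) recording: responsiveness (paired Wilcoxon on the
#' familiarity block), oscillation duration from the smoothed z-score
#' PSTH, orientation selectivity and double-Gaussian tuning width,
#' spatial-frequency DoG fit (preferred SF, FWHM, LSFS), and the
#' hyperbolic-ratio contrast fit (c50, exponent). Fitted parameters are
#' reported only for convergent fits with fit error < `fit_error_max`
#' (`NA` otherwise).
#'
#' @param rec One element of `cohort$recordings`.
#' @param fit_error_max Inclusion gate on the fit-error statistic.
#' @return Data frame, one row per unit.
#' @export
analyze_recording_units <- function(rec, fit_error_max = 0.7) {
  n <- nrow(rec$units)
  out <- vector("list", n)
  for (ui in seq_len(n)) {
    fam <- rec$spikes$familiar[[ui]]
    resp <- responsive_unit(fam)
    dur <- tryCatch({
      z <- zscore_psth(compute_psth(fam))
      oscillation_duration(z)
    }, error = function(e) NA_real_)

    ocurve <- make_tuning_curve(rec$spikes$orientation[[ui]],
                                rec$protocols$orientation)
    unit_osi <- osi(ocurve)
    ofit <- fit_direction_tuning(ocurve)
    sigma <- if (ofit$converged && is.finite(ofit$fit_error) &&
                 ofit$fit_error < fit_error_max) ofit$sigma else NA_real_
    pref_dir <- ocurve$levels[which.max(ocurve$mean)]

    scurve <- make_tuning_curve(rec$spikes$sf[[ui]], rec$protocols$sf)
    sfit <- fit_sf_tuning(scurve)
    fwhm <- if (sfit$converged && is.finite(sfit$fit_error) &&
                sfit$fit_error < fit_error_max) sfit$fwhm else NA_real_

    ccurve <- make_tuning_curve(rec$spikes$contrast[[ui]],
                                rec$protocols$contrast)
    cfit <- fit_contrast(ccurve)
    gate_c <- cfit$converged && is.finite(cfit$fit_error) &&
      cfit$fit_error < fit_error_max
    out[[ui]] <- data.frame(
      unit_id = rec$units$unit_id[ui],
      genotype = rec$genotype, condition = rec$condition,
      responsive = resp$responsive, responsive_p = resp$p_value,
      osc_duration_s = dur,
      osi = unit_osi, sigma = sigma, pref_direction = pref_dir,
      dir_fit_error = ofit$fit_error,
      pref_sf = sfit$pref_sf, fwhm = fwhm, lsfs = sfit$lsfs,
      sf_fit_error = sfit$fit_error,
      c50 = if (gate_c) cfit$c50 else NA_real_,
      n_exp = if (gate_c) cfit$n_exp else NA_real_,
      contrast_fit_error = cfit$fit_error,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Population decoding for each tuning protocol of a recording
#'
#' @param rec One element of `cohort$recordings`.
#' @param n_folds,n_repeats,min_test,seed Passed to [decode()].
#' @return Data frame with one row per protocol (`orientation`, `sf`,
#'   `contrast`): accuracy mean, SEM, chance level, class count.
#' @export
analyze_recording_decoding <- function(rec, n_folds = 4, n_repeats = 5,
                                       min_test = 30, seed = 1L) {
  rows <- lapply(c("orientation", "sf", "contrast"), function(pn) {
    pc <- build_counts(rec$spikes[[pn]], rec$protocols[[pn]])
    dr <- decode(pc, n_folds = n_folds, n_repeats = n_repeats,
                 min_test = min_test, seed = seed)
    data.frame(genotype = rec$genotype, condition = rec$condition,
               protocol = pn, accuracy = dr$mean, sem = dr$sem,
               chance = dr$chance, n_classes = dr$n_classes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full cohort analysis
#'
#' Per-unit tables and decoding results for every recording of a
#' cohort; the analysis reads only the simulated observables (spikes,
#' trial tables, LFP), never the ground-truth parameters.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param decoding Run the decoding stage.
#' @param seed Seed for the cross-validation shuffles.
#' @param ... Passed to [analyze_recording_decoding()].
#' @return List with `units` (row-bound per-unit table) and `decoding`
#'   (row-bound decoding table or `NULL`).
#' @export
analyze_cohort <- function(cohort, decoding = TRUE, seed = 1L, ...) {
  stopifnot(inherits(cohort, "cohort"))
  units <- do.call(rbind, lapply(cohort$recordings, analyze_recording_units))
  rownames(units) <- NULL
  dec <- NULL
  if (decoding) {
    dec <- do.call(rbind, lapply(cohort$recordings, function(rec)
      analyze_recording_decoding(rec, seed = seed, ...)))
    rownames(dec) <- NULL
  }
  list(units = units, decoding = dec)
}

#' Genotype comparisons of the per-unit metrics
#'
#' Applies [compare_groups()] (Kruskal-Wallis + pairwise Mann-Whitney)
#' across genotypes, within one condition, for each requested unit-level
#' metric.
#'
#' @param unit_table The `units` table from [analyze_cohort()].
#' @param condition Condition to compare within.
#' @param metrics Metric columns to compare.
#' @return Named list of `group_comparison` objects (metrics with fewer
#'   than 2 usable groups are dropped).
#' @export
compare_genotypes <- function(unit_table, condition = "post_familiar",
                              metrics = c("osc_duration_s", "osi", "sigma",
                                          "lsfs", "c50", "n_exp")) {
  sub <- unit_table[unit_table$condition == condition, , drop = FALSE]
  out <- list()
  for (m in metrics) {
    samples <- split(sub[[m]], sub$genotype)
    samples <- lapply(samples, function(x) x[is.finite(x)])
    samples <- samples[lengths(samples) >= 2]
    if (length(samples) >= 2) {
      out[[m]] <- compare_groups(samples, metric = m)
    }
  }
  out
}

#' Split a concatenated session trial table into its protocols
#'
#' Recordings written to disk concatenate the familiarity block and the
#' three tuning protocols on one session clock; this recovers the
#' protocol membership from the stimulus parameters: the familiarity
#' block is the 0.4-s familiar grating (or the checkerboard in the
#' novel condition), orientation tuning the 0.5-s drifting gratings,
#' spatial-frequency tuning the noise stimuli, and contrast tuning the
#' static gratings.
#'
#' @param trials A session `trial_table`.
#' @return Named list of row-index vectors (`familiar`, `orientation`,
#'   `sf`, `contrast`).
#' @export
split_protocols <- function(trials) {
  kind <- trials$kind
  dur <- trials$duration_s
  list(familiar = which(kind == "checkerboard" |
                          (kind == "drifting_grating" & abs(dur - 0.4) < 1e-9)),
       orientation = which(kind == "drifting_grating" & abs(dur - 0.5) < 1e-9),
       sf = which(kind == "sf_noise"),
       contrast = which(kind == "static_grating"))
}

#' Analyse a recording directory (sorted-output layout)
#'
#' Runs the per-unit pipeline directly off a recording written in the
#' Phy-style layout: reads spike times / cluster labels, keeps only
#' clusters labelled `"good"`, re-epochs each cluster around the trial
#' onsets of each protocol, and applies [analyze_recording_units()].
#' The ground-truth sidecar is never read.
#'
#' @param dir Recording directory (as written by [write_cohort()]).
#' @param epoch_window Window around onset, seconds.
#' @param ... Passed to [analyze_recording_units()].
#' @return Per-unit metric data frame.
#' @export
analyze_recording_dir <- function(dir, epoch_window = c(-0.5, 2.0), ...) {
  rec <- read_recording(dir, read_lfp = FALSE)
  base <- basename(dir)
  genotype <- sub("_.*$", "", base)
  condition <- sub("^[^_]*_", "", base)
  good <- rec$cluster_group$cluster_id[rec$cluster_group$group == "good"]
  idx <- split_protocols(rec$trials)
  protocols <- lapply(idx, function(i) rec$trials[i, , drop = FALSE])
  spikes <- lapply(protocols, function(tt)
    lapply(good, function(cl) epoch_cluster(rec, cl, epoch_window, tt)))
  unit_ids <- if (!is.null(rec$unit_ids)) rec$unit_ids[good] else
    paste0(base, "_c", good)
  rec_obj <- list(genotype = genotype, condition = condition,
                  units = data.frame(unit_id = unit_ids),
                  protocols = protocols, spikes = spikes)
  analyze_recording_units(rec_obj, ...)
}
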