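#' Write one synthetic recording in a Phy-style layout
#'
#' Writes a recording directory matching the columnar layout produced by
#' spike sorting (Kilosort/Phy): `spike_times.txt` (integer sample
#' indices, ascending), `spike_clusters.txt` (one cluster label per
#' spike), `cluster_group.tsv` (cluster quality; only `"good"` clusters
#' are analysed), the LFP as flat binary float32 (`lfp.dat`,
#' channel-interleaved) with a JSON sidecar (`lfp.json`: sampling rate,
#' channel count, channel order = depth order), the trial table as CSV,
#' and the generator's ground truth as a sidecar TSV that the analysis
#' path never reads.
#'
#' @param dir Output directory (created if needed).
#' @param units Ground-truth unit table ([sample_units()]).
#' @param spikes Named list of [epoched_spikes()], one per unit, names =
#'   `units$unit_id`.
#' @param lfp An `lfp_recording`, or `NULL` to skip.
#' @param trials The `trial_table` the spikes were simulated over.
#' @param spike_fs_hz Sample rate used to express spike times as integer
#'   samples (acquisition clock).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(dir, units, spikes, lfp, trials,
                            spike_fs_hz = 30000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  all_samples <- integer(0)
  all_clusters <- integer(0)
  for (k in seq_along(spikes)) {
    ep <- spikes[[k]]
    abs_t <- unlist(lapply(seq_along(ep$trials), function(i)
      trials$onset_s[i] + ep$trials[[i]]), use.names = FALSE)
    if (length(abs_t)) {
      all_samples <- c(all_samples, as.integer(round(abs_t * spike_fs_hz)))
      all_clusters <- c(all_clusters, rep(k, length(abs_t)))
    }
  }
  ord <- order(all_samples, all_clusters)
  writeLines(as.character(all_samples[ord]), file.path(dir, "spike_times.txt"))
  writeLines(as.character(all_clusters[ord]),
             file.path(dir, "spike_clusters.txt"))
  cg <- data.frame(cluster_id = seq_along(spikes), group = "good")
  utils::write.table(cg, file.path(dir, "cluster_group.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_trial_table(trials, file.path(dir, "trials.csv"))
  utils::write.table(as.data.frame(units),
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(spike_fs_hz = spike_fs_hz,
               epoch_window = spikes[[1]]$window,
               unit_ids = as.character(units$unit_id))
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(lfp)) {
    con <- file(file.path(dir, "lfp.dat"), "wb")
    on.exit(close(con), add = TRUE)
    # channel-interleaved: sample 1 ch 1..C, sample 2 ch 1..C, ...
    writeBin(as.numeric(t(lfp$data)), con, size = 4, endian = "little")
    jsonlite::write_json(
      list(fs_hz = lfp$fs_hz, n_channels = lfp$n_channels,
           dtype = "float32", channel_order = "depth"),
      file.path(dir, "lfp.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Recording directory.
#' @param read_lfp Whether to load the LFP binary.
#' @return List with `spike_samples`, `spike_clusters`, `cluster_group`,
#'   `trials`, `spike_fs_hz`, and (if present and requested) `lfp`.
#' @export
read_recording <- function(dir, read_lfp = TRUE) {
  if (!dir.exists(dir)) stop("no such recording directory: ", dir)
  meta <- jsonlite::read_json(file.path(dir, "recording.json"),
                              simplifyVector = TRUE)
  out <- list(
    spike_samples = as.integer(readLines(file.path(dir, "spike_times.txt"))),
    spike_clusters = as.integer(readLines(file.path(dir,
                                                    "spike_clusters.txt"))),
    cluster_group = utils::read.delim(file.path(dir, "cluster_group.tsv"),
                                      stringsAsFactors = FALSE),
    trials = read_trial_table(file.path(dir, "trials.csv")),
    spike_fs_hz = meta$spike_fs_hz,
    unit_ids = meta$unit_ids)
  lfp_json <- file.path(dir, "lfp.json")
  if (read_lfp && file.exists(lfp_json)) {
    lmeta <- jsonlite::read_json(lfp_json, simplifyVector = TRUE)
    n <- file.size(file.path(dir, "lfp.dat")) / 4
    con <- file(file.path(dir, "lfp.dat"), "rb")
    on.exit(close(con), add = TRUE)
    v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    out$lfp <- structure(
      list(data = matrix(v, ncol = lmeta$n_channels, byrow = TRUE),
           fs_hz = lmeta$fs_hz, n_channels = lmeta$n_channels),
      class = "lfp_recording")
  }
  out
}

#' Re-epoch sorted spikes for one cluster
#'
#' Converts absolute sample-clock spike times back to per-trial epoched
#' times for one cluster label — the entry point from the sorted-output
#' layout into the single-unit analyses.
#'
#' @param rec A list from [read_recording()] (or equivalent fields).
#' @param cluster Cluster label to extract.
#' @param epoch_window Window around onset, seconds.
#' @param trials Trial table to epoch over; defaults to the recording's
#'   full table (pass a subset to epoch one protocol).
#' @return An [epoched_spikes()] object.
#' @export
epoch_cluster <- function(rec, cluster, epoch_window = c(-0.5, 2.0),
                          trials = NULL) {
  if (is.null(trials)) trials <- rec$trials
  t_abs <- rec$spike_samples[rec$spike_clusters == cluster] / rec$spike_fs_hz
  trials <- lapply(trials$onset_s, function(on) {
    rel <- t_abs - on
    rel[rel >= epoch_window[1] & rel <= epoch_window[2]]
  })
  epoched_spikes(trials, epoch_window)
}

# Concatenate a recording's protocols on a single session clock: each
# protocol's onsets are offset past the previous protocol's last epoch,
# with a 10-s gap, and the per-unit epoched spikes are concatenated in
# the same trial order.
flatten_recording <- function(rec, gap_s = 10) {
  offset <- 0
  tabs <- list()
  n_units <- nrow(rec$units)
  spikes <- replicate(n_units, list(trials = list()), simplify = FALSE)
  window <- rec$spikes[[1]][[1]]$window
  std_cols <- c("trial_index", "onset_s", "kind", "direction_deg", "sf_cpd",
                "tf_hz", "contrast", "duration_s", "condition")
  for (pn in names(rec$protocols)) {
    tt <- as.data.frame(rec$protocols[[pn]])[, std_cols]
    tt$onset_s <- tt$onset_s + offset
    tabs[[pn]] <- tt
    for (ui in seq_len(n_units)) {
      spikes[[ui]]$trials <- c(spikes[[ui]]$trials,
                               rec$spikes[[pn]][[ui]]$trials)
    }
    offset <- max(tt$onset_s) + window[2] + gap_s
  }
  combined <- do.call(rbind, tabs)
  combined$trial_index <- seq_len(nrow(combined))
  rownames(combined) <- NULL
  class(combined) <- c("trial_table", "data.frame")
  list(trials = combined,
       spikes = lapply(spikes, function(s) epoched_spikes(s$trials, window)))
}

#' Write a full cohort (genotype x condition recordings)
#'
#' One recording directory per genotype x condition, named
#' `<genotype>_<condition>`; each recording's protocols are concatenated
#' on a single session clock (as spike sorting of concatenated sessions
#' would yield) before writing in the Phy-style layout.
#'
#' @param cohort A cohort list from [simulate_cohort()].
#' @param out_dir Output root.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  for (rec in cohort$recordings) {
    flat <- flatten_recording(rec)
    write_recording(file.path(out_dir,
                              paste0(rec$genotype, "_", rec$condition)),
                    rec$units, flat$spikes, rec$lfp, flat$trials)
  }
  invisible(out_dir)
}
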