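#' Population spike-count matrix for decoding
#'
#' Per-trial spike counts of each unit in a count window (default
#' 0.05-0.5 s after stimulus onset), plus the per-trial stimulus label.
#'
#' @param spikes_per_unit List of [epoched_spikes()], all over the same
#'   trial set (same row order as `trials`).
#' @param trials The shared `trial_table`.
#' @param level_var Label column; inferred from the trial kinds when
#'   `NULL` (as in [make_tuning_curve()]).
#' @param window Count window, seconds relative to onset.
#' @return A `population_counts`: `counts` (trials x units integer
#'   matrix), `labels` (factor), `window`.
#' @export
build_counts <- function(spikes_per_unit, trials, level_var = NULL,
                         window = c(0.05, 0.5)) {
  n_trials <- nrow(trials)
  ok <- vapply(spikes_per_unit, function(s)
    inherits(s, "epoched_spikes") && s$n_trials == n_trials, logical(1))
  if (!all(ok)) stop("all units must share the trial set")
  if (is.null(level_var)) {
    level_var <- switch(trials$kind[1],
                        drifting_grating = "direction_deg",
                        sf_noise = "sf_cpd",
                        static_grating = "contrast",
                        stop("cannot infer label variable"))
  }
  counts <- vapply(spikes_per_unit, function(s)
    vapply(s$trials, function(t)
      sum(t >= window[1] & t < window[2]), numeric(1)),
    numeric(n_trials))
  counts <- matrix(as.integer(counts), nrow = n_trials)
  structure(list(counts = counts,
                 labels = factor(trials[[level_var]]),
                 window = window),
            class = "population_counts")
}

# Stratified fold assignment: within each class, trials are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Decode stimulus identity from population spike counts
#'
#' Linear discriminant analysis with repeated stratified k-fold
#' cross-validation (default 4 folds, 5 repeats with reshuffled folds).
#' The fold count must keep every test fold at or above `min_test`
#' trials; a violation raises an error naming the constraint so the
#' caller can lower the fold count. Units with zero variance in a
#' training split are dropped from that split; collinearity warnings
#' from the discriminant solver are suppressed (expected when units
#' outnumber trials).
#'
#' @param counts A [build_counts()] result.
#' @param n_folds Folds per repeat.
#' @param n_repeats Repeats (fold reshuffles).
#' @param min_test Minimum test-fold size.
#' @param seed Integer seed.
#' @return A `decoding_result`: `accuracies` (one per fold x repeat),
#'   `mean`, `sem`, `n_classes`, `chance` (= 1 / n_classes).
#' @export
decode <- function(counts, n_folds = 4, n_repeats = 5, min_test = 30,
                   seed = 1L) {
  stopifnot(inherits(counts, "population_counts"))
  labels <- counts$labels
  x <- counts$counts
  tab <- table(labels)
  if (any(tab < n_folds)) {
    stop("every class needs at least `n_folds` trials")
  }
  min_fold <- sum(floor(tab / n_folds))
  if (min_fold < min_test) {
    stop(sprintf(paste0("test folds would hold %d trials, below the ",
                        "minimum test size of %d; lower `n_folds` or ",
                        "`min_test`"), min_fold, min_test))
  }
  set.seed(seed)
  acc <- numeric(0)
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- fold == f
      keep <- apply(x[tr, , drop = FALSE], 2, stats::var) > 0
      if (!any(keep)) { acc <- c(acc, mean(tab / sum(tab))); next }
      xtr <- x[tr, keep, drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(MASS::lda(xtr, grouping = labels[tr])),
        error = function(e) NULL)
      if (is.null(fit)) {
        # zero within-class variance (perfectly separated counts): a tiny
        # symmetric jitter - above the solver's constant-variable
        # tolerance, far below one spike - makes the covariance estimable
        # without moving the decision boundary
        xtr <- xtr + stats::rnorm(length(xtr)) * 1e-3
        fit <- suppressWarnings(MASS::lda(xtr, grouping = labels[tr]))
      }
      pred <- stats::predict(fit, x[te, keep, drop = FALSE])$class
      acc <- c(acc, mean(pred == labels[te]))
    }
  }
  structure(list(accuracies = acc,
                 mean = mean(acc),
                 sem = stats::sd(acc) / sqrt(length(acc)),
                 n_classes = nlevels(labels),
                 chance = 1 / nlevels(labels),
                 n_folds = n_folds, n_repeats = n_repeats),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> accuracy %.1f +/- %.1f %% (chance %.1f %%, %dx%d CV)\n",
    100 * x$mean, 100 * x$sem, 100 * x$chance, x$n_folds, x$n_repeats))
  invisible(x)
}
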