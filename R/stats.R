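#' Nonparametric group comparison: Kruskal-Wallis + pairwise Mann-Whitney
#'
#' The comparison pattern used throughout the pipeline for unit-level
#' metrics across genotypes or conditions: an omnibus Kruskal-Wallis
#' rank-sum test over all groups, followed by two-sided pairwise
#' Mann-Whitney U tests for every group pair, without multiplicity
#' correction by default (set `p_adjust = "holm"` to correct). The
#' effect direction per pair is the sign of the difference in group
#' medians.
#'
#' @param samples Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 finite values).
#' @param metric Metric name carried in the result.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method
#'   applied to the pairwise p-values.
#' @return A `group_comparison`: `metric`, `n` (per group),
#'   `omnibus_stat`, `omnibus_p`, and a `pairwise` data frame
#'   (`group1`, `group2`, `u_stat`, `p_value`, `direction`).
#' @export
compare_groups <- function(samples, metric = "metric", p_adjust = "none") {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  samples <- lapply(samples, function(x) x[is.finite(x)])
  ns <- lengths(samples)
  if (any(ns < 2)) stop("every group needs >= 2 finite values")
  pooled <- unlist(samples, use.names = FALSE)
  if (stats::var(pooled) == 0) {
    stop("all values identical across groups; rank tests undefined")
  }
  kw <- stats::kruskal.test(samples)
  pairs <- utils::combn(names(samples), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   u_stat = NA_real_, p_value = NA_real_,
                   direction = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- samples[[pairs[1, i]]]; b <- samples[[pairs[2, i]]]
    mw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    pw$u_stat[i] <- unname(mw$statistic)
    pw$p_value[i] <- mw$p.value
    pw$direction[i] <- sign(stats::median(a) - stats::median(b))
  }
  if (p_adjust != "none") {
    pw$p_value <- stats::p.adjust(pw$p_value, method = p_adjust)
  }
  structure(list(metric = metric, n = ns,
                 omnibus_stat = unname(kw$statistic),
                 omnibus_p = kw$p.value,
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Kruskal-Wallis chi^2 = %.3g, p = %.3g\n",
              x$metric, x$omnibus_stat, x$omnibus_p))
  cat(sprintf("  n = %s\n",
              paste(sprintf("%s:%d", names(x$n), x$n), collapse = ", ")))
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("  %s vs %s: U = %.4g, p = %.3g (%s)\n", r$group1, r$group2,
                r$u_stat, r$p_value,
                c("-1" = "lower", "0" = "equal", "1" = "higher")[
                  as.character(r$direction)]))
  }
  invisible(x)
}
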