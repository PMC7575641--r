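#' Cohort configuration: per-genotype, per-condition unit priors
#'
#' Describes the statistical structure of a synthetic cohort: for each
#' genotype (WT, HET, KO) and recording condition (`pre`,
#' `post_familiar`, `post_novel`) a set of priors from which ground-truth
#' unit parameters are drawn. The defaults encode the experience- and
#' genotype-dependent effect directions the analyses are designed to
#' detect: after perceptual experience, KO units carry longer
#' familiarity-evoked oscillations, broader direction-tuning width, and
#' weaker low-spatial-frequency suppression than WT; HET carries higher
#' semisaturation contrast (c50) and lower exponent; naive (`pre`)
#' genotypes are indistinguishable. Each prior is a `c(mean, sd)` pair;
#' draws are truncated to valid ranges. Setting every `sd` to 0 yields
#' identical units at the prior means.
#'
#' @param n_units Units per genotype per condition.
#' @param epoch_window Epoch window around stimulus onset, seconds
#'   (pre-onset baseline length and post-onset length).
#' @return A `cohort_config` object (nested named list).
#' @export
default_cohort_config <- function(n_units = 40, epoch_window = c(-0.5, 2.0)) {
  base <- list(
    baseline_rate = c(3, 1),        # Hz
    Rp = c(25, 6),                  # preferred-direction amplitude, Hz
    rn_frac = c(0.3, 0.1),          # Rn as a fraction of Rp
    sigma = c(25, 5),               # direction tuning width, deg
    cardinal_bias = 0.55,           # P(theta_p near a cardinal direction)
    theta_jitter = c(0, 8),         # deg jitter around the chosen centre
    Ke = c(20, 5),                  # SF excitatory amplitude, Hz
    mu_e = c(log2(0.05), 0.6),      # SF centre, log2 cpd
    sig_e = c(1.2, 0.2),            # SF widths, octaves
    lsfs = c(0.35, 0.10),           # target low-SF / preferred-SF ratio
    Rmax = c(20, 5),                # contrast model amplitude, Hz
    c50 = c(0.30, 0.08),
    n_exp = c(2.2, 0.4),
    novel_amp = c(18, 5),           # checkerboard response amplitude, Hz
    f_osc = c(6, 0.5),              # familiarity oscillation frequency, Hz
    mod_depth = c(0, 0),            # oscillation modulation depth
    osc_duration = c(0, 0),         # oscillation duration, s
    osc_enabled = FALSE)

  tweak <- function(p, ...) utils::modifyList(p, list(...))
  post_wt <- tweak(base, osc_enabled = TRUE, mod_depth = c(0.8, 0.05),
                   osc_duration = c(0.7, 0.15))
  priors <- list(
    WT = list(pre = base,
              post_familiar = post_wt,
              post_novel = tweak(base, cardinal_bias = 0.55)),
    HET = list(pre = tweak(base, cardinal_bias = 1 / 3),
               post_familiar = tweak(post_wt, osc_duration = c(1.0, 0.2),
                                     sigma = c(30, 6), c50 = c(0.45, 0.10),
                                     n_exp = c(1.6, 0.3),
                                     cardinal_bias = 0.5),
               post_novel = tweak(base, cardinal_bias = 0.5)),
    KO = list(pre = tweak(base, cardinal_bias = 1 / 3),
              post_familiar = tweak(post_wt, osc_duration = c(1.25, 0.2),
                                    sigma = c(42, 8), lsfs = c(0.65, 0.10),
                                    cardinal_bias = 1 / 3),
              post_novel = tweak(base, novel_amp = c(10, 4),
                                 cardinal_bias = 1 / 3)))
  structure(list(genotypes = names(priors),
                 conditions = c("pre", "post_familiar", "post_novel"),
                 n_units = n_units,
                 epoch_window = epoch_window,
                 priors = priors),
            class = "cohort_config")
}

# Truncated-normal draw; sd = 0 returns the mean exactly.
rtrunc_norm <- function(n, prior, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, prior[1], prior[2])
  pmin(pmax(x, lo), hi)
}

#' Sample ground-truth units for one genotype and condition
#'
#' Draws `config$n_units` units from the genotype- and condition-specific
#' priors. Each unit carries every parameter of the generative model:
#' baseline rate, double-Gaussian direction tuning (`Rp`, `Rn`,
#' `theta_p`, `sigma`), difference-of-Gaussians spatial-frequency tuning
#' on a log2-cpd axis (`Ke`, `Ki`, `mu_e`, `mu_i`, `sig_e`, `sig_i`),
#' hyperbolic-ratio contrast response (`Rmax`, `n_exp`, `c50`), the
#' checkerboard (novel-stimulus) amplitude, and the familiarity
#' oscillation (`f_osc`, `mod_depth`, `osc_duration`, `osc_enabled`).
#' The inhibitory DoG component is anchored at the lowest tested spatial
#' frequency and its amplitude `Ki` is solved per unit so that the
#' model's low-SF/preferred-SF response ratio equals the unit's drawn
#' `lsfs` target, which is how the priors control low-spatial-frequency
#' suppression.
#'
#' @param config A [default_cohort_config()] object.
#' @param genotype Genotype label present in `config`.
#' @param condition Condition label present in `config`.
#' @param seed Integer seed; draws are deterministic under it.
#' @return Data frame of units (`ground_truth_units`), one row per unit.
#' @export
sample_units <- function(config, genotype, condition, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (!genotype %in% names(config$priors)) {
    stop("unknown genotype: ", genotype)
  }
  if (!condition %in% names(config$priors[[genotype]])) {
    stop("unknown condition: ", condition)
  }
  p <- config$priors[[genotype]][[condition]]
  n <- config$n_units
  set.seed(seed)

  baseline <- rtrunc_norm(n, p$baseline_rate, lo = 0.5)
  Rp <- rtrunc_norm(n, p$Rp, lo = 1)
  Rn <- Rp * rtrunc_norm(n, p$rn_frac, lo = 0, hi = 1)
  sigma <- rtrunc_norm(n, p$sigma, lo = 8, hi = 90)
  cardinal <- stats::runif(n) < p$cardinal_bias
  centre <- ifelse(cardinal,
                   sample(c(0, 90, 180, 270), n, replace = TRUE),
                   stats::runif(n, 0, 360))
  theta_p <- (centre + rtrunc_norm(n, p$theta_jitter)) %% 360

  Ke <- rtrunc_norm(n, p$Ke, lo = 2)
  mu_e <- rtrunc_norm(n, p$mu_e)
  sig_e <- rtrunc_norm(n, p$sig_e, lo = 0.4)
  lsfs_target <- rtrunc_norm(n, p$lsfs, lo = 0.05, hi = 0.95)
  x_low <- log2(min(tuning_levels("sf")))
  mu_i <- rep(x_low, n)
  sig_i <- rep(1.0, n)
  # Solve Ki so that response(lowest SF) = lsfs_target * response(mu_e):
  # at x_low the inhibitory Gaussian is 1, at mu_e it is g_i(mu_e). A
  # negative Ki is a low-SF shoulder (suppression weaker than the
  # excitatory tail alone would give), which is how high-LSFS units arise.
  g_e_low <- exp(-(x_low - mu_e)^2 / (2 * sig_e^2))
  g_i_pk <- exp(-(mu_e - x_low)^2 / (2 * sig_i^2))
  Ki <- Ke * (g_e_low - lsfs_target) / (1 - lsfs_target * g_i_pk)

  Rmax <- rtrunc_norm(n, p$Rmax, lo = 2)
  c50 <- rtrunc_norm(n, p$c50, lo = 0.05, hi = 1)
  n_exp <- rtrunc_norm(n, p$n_exp, lo = 0.8, hi = 5)
  novel_amp <- rtrunc_norm(n, p$novel_amp, lo = 0)

  f_osc <- rtrunc_norm(n, p$f_osc, lo = 4, hi = 8)
  mod_depth <- rtrunc_norm(n, p$mod_depth, lo = 0, hi = 1)
  osc_duration <- rtrunc_norm(n, p$osc_duration, lo = 0, hi = 1.8)

  out <- data.frame(
    unit_id = sprintf("%s_%s_u%03d", genotype, condition, seq_len(n)),
    genotype = genotype, condition = condition,
    baseline_rate = baseline, Rp = Rp, Rn = Rn, theta_p = theta_p,
    sigma = sigma, Ke = Ke, Ki = Ki, mu_e = mu_e, mu_i = mu_i,
    sig_e = sig_e, sig_i = sig_i, lsfs_target = lsfs_target,
    Rmax = Rmax, c50 = c50, n_exp = n_exp, novel_amp = novel_amp,
    f_osc = f_osc, mod_depth = mod_depth, osc_duration = osc_duration,
    osc_enabled = p$osc_enabled,
    stringsAsFactors = FALSE)
  class(out) <- c("ground_truth_units", "data.frame")
  out
}
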