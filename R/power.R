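#' Specify a two-group design for minimal-effect / equivalence power analysis
#'
#' Bundles the quantities the preregistered design analysis needs: the assumed
#' true raw-scale group difference, the common group SD, per-group n, the
#' smallest effect size of interest (SESOI) on the raw scale, symmetric
#' equivalence bounds, the CI level used by the decision rules, and the
#' Monte-Carlo settings.
#'
#' @param true_difference Assumed true mean difference (outcome units).
#' @param group_sd Common within-group SD (> 0).
#' @param n_per_group Participants per group (>= 2).
#' @param sesoi Smallest effect size of interest, raw scale (> 0).
#' @param equivalence_bound Half-width b of the symmetric equivalence region
#'   (-b, b); defaults to `sesoi`.
#' @param ci_level Confidence level of the interval the decision rules use
#'   (default 0.80, i.e. TOST alpha 0.10).
#' @param n_simulations Monte-Carlo replicates (default 10000).
#' @param seed Integer seed.
#' @return An object of class `power_design`.
#' @export
power_design <- function(true_difference, group_sd, n_per_group, sesoi,
                         equivalence_bound = sesoi, ci_level = 0.80,
                         n_simulations = 10000L, seed = 1L) {
  stopifnot(group_sd > 0, n_per_group >= 2, sesoi > 0, equivalence_bound > 0,
            ci_level > 0, ci_level < 1, n_simulations >= 1)
  structure(
    list(true_difference = true_difference, group_sd = group_sd,
         n_per_group = as.integer(n_per_group), sesoi = sesoi,
         equivalence_bound = equivalence_bound, ci_level = ci_level,
         n_simulations = as.integer(n_simulations), seed = as.integer(seed)),
    class = "power_design"
  )
}

# Welch CIs for n_simulations two-group experiments, vectorized over sims.
# Returns a matrix with columns lower/upper.
welch_ci_sims <- function(design) {
  n <- design$n_per_group
  nsim <- design$n_simulations
  a <- matrix(stats::rnorm(n * nsim, mean = design$true_difference,
                           sd = design$group_sd), nrow = n)
  b <- matrix(stats::rnorm(n * nsim, mean = 0, sd = design$group_sd), nrow = n)
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = n))^2) / (n - 1)
  vb <- colSums((b - rep(mb, each = n))^2) / (n - 1)
  se2a <- va / n
  se2b <- vb / n
  se <- sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (n - 1) + se2b^2 / (n - 1))
  tcrit <- stats::qt(1 - (1 - design$ci_level) / 2, df)
  diff <- ma - mb
  cbind(lower = diff - tcrit * se, upper = diff + tcrit * se)
}

power_result <- function(successes, n_simulations, kind) {
  p <- successes / n_simulations
  structure(
    list(power = p,
         n_simulations = n_simulations,
         mc_standard_error = sqrt(p * (1 - p) / n_simulations),
         kind = kind),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s power: %.4f (MC SE %.4f, %d simulations)\n",
              x$kind, x$power, x$mc_standard_error, x$n_simulations))
  invisible(x)
}

#' Simulated power of the minimal-effect test
#'
#' Monte-Carlo power of the preregistered minimal-effect decision rule: for
#' each simulated experiment two groups of `n_per_group` normal deviates are
#' drawn (means differing by `true_difference`, common `group_sd`), the Welch
#' confidence interval for the mean difference is formed at `ci_level`, and a
#' success is recorded when the CI lower bound exceeds the SESOI.
#'
#' @param design A [power_design()].
#' @return A `power_result` with fields `power`, `mc_standard_error`,
#'   `n_simulations`, `kind`.
#' @examples
#' d <- power_design(0.15, 0.30, 100, sesoi = 0.06, n_simulations = 2000)
#' simulate_minimal_effect_power(d)  # ~0.80
#' @export
simulate_minimal_effect_power <- function(design) {
  stopifnot(inherits(design, "power_design"))
  withr_seed(design$seed, {
    ci <- welch_ci_sims(design)
    power_result(sum(ci[, "lower"] > design$sesoi), design$n_simulations,
                 "minimal-effect")
  })
}

#' Simulated probability of declaring equivalence
#'
#' As [simulate_minimal_effect_power()], but a success is recorded when the
#' Welch CI at `ci_level` lies strictly inside the equivalence bounds
#' (-b, b). Run with `true_difference = 0` this is the probability of
#' (correctly) declaring equivalence under the null.
#'
#' @inheritParams simulate_minimal_effect_power
#' @return A `power_result`.
#' @export
simulate_equivalence_power <- function(design) {
  stopifnot(inherits(design, "power_design"))
  b <- design$equivalence_bound
  withr_seed(design$seed, {
    ci <- welch_ci_sims(design)
    power_result(sum(ci[, "lower"] > -b & ci[, "upper"] < b),
                 design$n_simulations, "equivalence")
  })
}

#' Closed-form normal-approximation oracle for the simulated powers
#'
#' With SE = group_sd * sqrt(2/n) and z* the (1 + ci_level)/2 normal quantile,
#' the minimal-effect power is Phi((delta - sesoi)/SE - z*) and the
#' equivalence probability is Phi((b - delta)/SE - z*) - Phi((-b - delta)/SE + z*)
#' (floored at 0). Used as an independent cross-check of the Monte-Carlo
#' routines; at the design sizes used here the t-vs-z difference is
#' negligible.
#'
#' @inheritParams simulate_minimal_effect_power
#' @return Named numeric vector `c(power_minimal_effect =, power_equivalence =)`.
#' @export
analytic_power_oracle <- function(design) {
  stopifnot(inherits(design, "power_design"))
  se <- design$group_sd * sqrt(2 / design$n_per_group)
  zs <- stats::qnorm(1 - (1 - design$ci_level) / 2)
  delta <- design$true_difference
  b <- design$equivalence_bound
  p_min <- stats::pnorm((delta - design$sesoi) / se - zs)
  p_eq <- max(0, stats::pnorm((b - delta) / se - zs) -
                 stats::pnorm((-b - delta) / se + zs))
  c(power_minimal_effect = p_min, power_equivalence = p_eq)
}

#' Derive the SESOI on criterion c from a one-hit-one-false-alarm shift
#'
#' Implements the design's definition of the smallest effect size of interest:
#' a randomly chosen fraction of "receptive" participants make `extra_hits`
#' more hit responses and `extra_false_alarms` more false-alarm responses than
#' their baseline counts (capped at the number of old/new items), everyone
#' else is unchanged. The per-participant change in criterion c (after minus
#' before, `half_count` correction) is the simulated between-group c
#' difference; its cohort mean and SD summarize the SESOI.
#'
#' Signs follow the SDT parameterization: extra "old" responses (the
#' omission-feedback direction) lower c, i.e. the mean delta is negative.
#'
#' @param baseline_counts List of `recognition_counts`, one per participant.
#' @param receptive_fraction Fraction of the cohort shifted (0 < f <= 1;
#'   `0` is allowed and shifts no one).
#' @param extra_hits,extra_false_alarms Integer response shifts (default 1).
#' @param seed Integer seed for selecting the receptive subset.
#' @param policy Extreme-rate policy passed to [sdt_indices()].
#' @return An object of class `sesoi_summary`: list with `mean_delta_c`,
#'   `sd_delta_c`, `per_participant_deltas`, `shifted` (logical vector).
#' @export
derive_sesoi <- function(baseline_counts, receptive_fraction = 0.25,
                         extra_hits = 1L, extra_false_alarms = 1L, seed = 1L,
                         policy = "half_count") {
  if (length(baseline_counts) == 0L) stop("empty cohort")
  stopifnot(all(vapply(baseline_counts, inherits, logical(1), "recognition_counts")),
            receptive_fraction >= 0, receptive_fraction <= 1)
  n <- length(baseline_counts)
  n_shift <- round(receptive_fraction * n)
  shifted <- rep(FALSE, n)
  if (n_shift > 0L) {
    shifted[withr_seed(seed, sample.int(n, n_shift))] <- TRUE
  }
  at_ceiling <- vapply(baseline_counts, function(ct) {
    ct$hits >= ct$n_old && ct$false_alarms >= ct$n_new
  }, logical(1))
  if (any(at_ceiling & shifted) && (extra_hits > 0 || extra_false_alarms > 0)) {
    warning("some shifted participants are at ceiling; their shift is vacuous")
  }
  deltas <- vapply(seq_len(n), function(i) {
    ct <- baseline_counts[[i]]
    if (!shifted[i]) return(0)
    h2 <- min(ct$hits + extra_hits, ct$n_old)
    f2 <- min(ct$false_alarms + extra_false_alarms, ct$n_new)
    after <- recognition_counts(h2, ct$n_old - h2, f2, ct$n_new - f2)
    sdt_indices(after, policy)$criterion_c - sdt_indices(ct, policy)$criterion_c
  }, numeric(1))
  structure(
    list(mean_delta_c = mean(deltas),
         sd_delta_c = stats::sd(deltas),
         per_participant_deltas = deltas,
         shifted = shifted),
    class = "sesoi_summary"
  )
}

#' Raw regression slope implied by a correlation
#'
#' Converts a correlation between a predictor and an outcome into the simple
#' linear-regression slope on the raw scales: slope = r * sd_outcome /
#' sd_predictor. Used to translate the assumed distrust–criterion correlation
#' into criterion-c units per Likert unit.
#'
#' @param r Correlation (|r| <= 1).
#' @param sd_predictor,sd_outcome Standard deviations (> 0).
#' @return The raw-scale slope.
#' @examples
#' slope_from_correlation(0.25, 2.00, 0.30)  # 0.0375
#' @export
slope_from_correlation <- function(r, sd_predictor, sd_outcome) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  stopifnot(sd_predictor > 0, sd_outcome > 0)
  r * sd_outcome / sd_predictor
}
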