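#' Apply the preregistered participant exclusion rules
#'
#' Removes participants flagged by any of the exclusion rules (attention-check
#' failure, self-reported non-seriousness, having seen the materials before,
#' distrusting the feedback). Rules are applied as a union, so the result does
#' not depend on their order.
#'
#' @param participants Data.frame with one 0/1 (or logical) column per rule.
#' @param rules Character vector of flag-column names.
#' @return List with `participants` (filtered table) and `report`, an
#'   `exclusion_report`: `n_input`, `n_after_each_rule` (count remaining if
#'   that rule alone were applied), `n_final`, `excluded_ids` per rule.
#' @export
apply_exclusions <- function(participants,
                             rules = c("attention_fail", "not_serious",
                                       "seen_before", "distrusted_feedback")) {
  miss <- setdiff(rules, names(participants))
  if (length(miss) > 0L) {
    stop(sprintf("missing exclusion flag column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  ids <- participants$participant_id
  excluded_ids <- lapply(rules, function(r) {
    flag <- participants[[r]]
    if (anyNA(flag)) stop(sprintf("NA in exclusion flag column %s", r))
    ids[flag %in% c(1, TRUE)]
  })
  names(excluded_ids) <- rules
  all_excluded <- unique(unlist(excluded_ids))
  keep <- !ids %in% all_excluded
  report <- structure(
    list(n_input = length(ids),
         n_after_each_rule = vapply(excluded_ids, function(e) {
           length(ids) - length(e)
         }, integer(1)),
         n_final = sum(keep),
         excluded_ids = excluded_ids),
    class = "exclusion_report"
  )
  list(participants = participants[keep, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("exclusions: %d -> %d participants\n", x$n_input, x$n_final))
  for (r in names(x$excluded_ids)) {
    cat(sprintf("  %-20s %d flagged\n", r, length(x$excluded_ids[[r]])))
  }
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient k/(k-1) * (1 - sum of item variances /
#' variance of the total score). Undefined (error) when the total score has
#' zero variance.
#'
#' @param items Numeric matrix/data.frame, one row per respondent, one
#'   column per item.
#' @return Alpha (a scalar; 1 for perfectly correlated items).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  v_total <- stats::var(rowSums(items))
  if (v_total == 0) stop("total score has zero variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / v_total)
}

#' Score the trait memory-distrust scales
#'
#' The commission-distrust scale (MDS) has 20 items on 1..7; the
#' omission-distrust scale (SSMQ) has 18 items on -4..4 and is reverse-coded
#' (x -> -x) before averaging, so that on both scales a higher mean means
#' higher memory distrust. Internal consistency is Cronbach's alpha; the two
#' scale means are correlated with Pearson's r.
#'
#' @param mds Numeric matrix/data.frame, one row per respondent, 20 columns,
#'   values in 1..7.
#' @param ssmq Numeric matrix/data.frame, 18 columns, values in -4..4
#'   (raw, not yet reversed).
#' @return List with `mds_mean`, `ssmq_mean` (per-respondent, reversed),
#'   `alpha_mds`, `alpha_ssmq`, `pearson_r`.
#' @export
score_trait_scales <- function(mds, ssmq) {
  mds <- as.matrix(mds)
  ssmq <- as.matrix(ssmq)
  if (ncol(mds) != 20L) stop("commission-distrust scale must have 20 items")
  if (ncol(ssmq) != 18L) stop("omission-distrust scale must have 18 items")
  if (any(mds < 1 | mds > 7)) stop("commission-scale item outside 1..7")
  if (any(ssmq < -4 | ssmq > 4)) stop("omission-scale item outside -4..4")
  ssmq_rev <- -ssmq
  mds_mean <- rowMeans(mds)
  ssmq_mean <- rowMeans(ssmq_rev)
  list(mds_mean = mds_mean,
       ssmq_mean = ssmq_mean,
       alpha_mds = cronbach_alpha(mds),
       alpha_ssmq = cronbach_alpha(ssmq_rev),
       pearson_r = stats::cor(mds_mean, ssmq_mean))
}

# Invert the noncentral-F cdf in the noncentrality parameter.
ncp_from_f <- function(f, df1, df2, prob) {
  if (stats::pf(f, df1, df2, ncp = 0) < prob) return(0)
  upper <- max(f * df1 * 2, 10)
  while (stats::pf(f, df1, df2, ncp = upper) > prob) upper <- upper * 2
  stats::uniroot(function(l) stats::pf(f, df1, df2, ncp = l) - prob,
                 c(0, upper), tol = 1e-8)$root
}

#' One-way between-subjects ANOVA with eta-squared and its CI
#'
#' Classical fixed-effects decomposition; eta^2 = SS_between / SS_total with
#' a 95% confidence interval obtained by inverting the noncentral-F
#' distribution in the noncentrality parameter.
#'
#' @param values Numeric outcome vector (NAs dropped pairwise with groups).
#' @param groups Grouping vector (>= 2 groups, each n >= 2).
#' @param conf_level Confidence level of the eta-squared CI (default 0.95).
#' @return An `anova_result`: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `eta_squared`, `eta_squared_ci`, `ss` (between/within/total),
#'   `group_means`.
#' @export
oneway_anova_eta2 <- function(values, groups, conf_level = 0.95) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  grand <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  ss_total <- ss_between + ss_within
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (ss_within == 0 && ss_between == 0) stop("all values identical: F undefined")
  f <- (ss_between / df1) / (ss_within / df2)
  alpha <- 1 - conf_level
  lam_lo <- ncp_from_f(f, df1, df2, 1 - alpha / 2)
  lam_hi <- ncp_from_f(f, df1, df2, alpha / 2)
  eta_ci <- c(lam_lo, lam_hi) / (c(lam_lo, lam_hi) + df1 + df2 + 1)
  structure(
    list(f_statistic = f, df_between = df1, df_within = df2,
         p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
         eta_squared = ss_between / ss_total,
         eta_squared_ci = eta_ci,
         ss = c(between = ss_between, within = ss_within, total = ss_total),
         group_means = means),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.2f, p = %.3g, eta^2 = %.3f, CI (%.3f, %.3f)\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value,
              x$eta_squared, x$eta_squared_ci[1], x$eta_squared_ci[2]))
  invisible(x)
}

#' Welch two-one-sided equivalence test with the three-way decision rule
#'
#' Runs the TOST procedure with Welch (unequal-variance) t statistics against
#' symmetric bounds (-b, b) at level `alpha`, reports the (1 - 2 alpha)
#' confidence interval for the mean difference (group A minus group B), and
#' applies the preregistered decision rule: `minimal_effect_supported` when
#' the CI lower bound exceeds the SESOI; `equivalent` when the CI lies
#' strictly inside the bounds; otherwise `suspend_judgement`.
#'
#' @param group_a,group_b Either raw numeric vectors or summary lists
#'   `list(mean =, sd =, n =)`.
#' @param bound Positive half-width b of the equivalence region.
#' @param alpha TOST alpha (default 0.1, i.e. an 80% CI).
#' @param sesoi Smallest effect of interest for the minimal-effect decision
#'   (default: `bound`).
#' @return An `equivalence_result`: `mean_difference`, `se`, `welch_df`,
#'   `ci`, `ci_level`, `tost_t_lower`, `tost_t_upper`, `tost_p`, `decision`.
#' @export
welch_tost <- function(group_a, group_b, bound, alpha = 0.1, sesoi = bound) {
  if (bound <= 0) stop("equivalence bound must be positive")
  stopifnot(alpha > 0, alpha < 0.5)
  summ <- function(g) {
    if (is.list(g)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(g)))
      g
    } else {
      g <- g[!is.na(g)]
      list(mean = mean(g), sd = stats::sd(g), n = length(g))
    }
  }
  a <- summ(group_a)
  b <- summ(group_b)
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2")
  se2a <- a$sd^2 / a$n
  se2b <- b$sd^2 / b$n
  se <- sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  diff <- a$mean - b$mean
  t_lower <- (diff + bound) / se  # H0: diff <= -bound
  t_upper <- (diff - bound) / se  # H0: diff >= +bound
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  ci_level <- 1 - 2 * alpha
  tcrit <- stats::qt(1 - alpha, df)
  ci <- c(diff - tcrit * se, diff + tcrit * se)
  decision <- if (ci[1] > sesoi) {
    "minimal_effect_supported"
  } else if (ci[1] > -bound && ci[2] < bound) {
    "equivalent"
  } else {
    "suspend_judgement"
  }
  structure(
    list(mean_difference = diff, se = se, welch_df = df,
         ci = ci, ci_level = ci_level,
         tost_t_lower = t_lower, tost_t_upper = t_upper,
         tost_p = max(p_lower, p_upper),
         bound = bound, sesoi = sesoi, decision = decision),
    class = "equivalence_result"
  )
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "diff = %.3f, t(%.2f), %d%% CI (%.3f, %.3f), bounds +/-%.3f, TOST p = %.3g\n  decision: %s\n",
    x$mean_difference, x$welch_df, round(100 * x$ci_level), x$ci[1], x$ci[2],
    x$bound, x$tost_p, x$decision))
  invisible(x)
}

#' Simple linear regression with a 90% CI for the slope
#'
#' Ordinary least squares of `outcome` on `predictor`. The 90% CI matches the
#' one-sided SESOI comparison used for the preregistered regression slopes.
#'
#' @param outcome,predictor Numeric vectors (pairwise-complete, n >= 3).
#' @param conf_level CI level for the slope (default 0.90).
#' @return List with `slope`, `se`, `p_value`, `ci`, `intercept`, `n`,
#'   and the underlying `lm` fit.
#' @export
fit_linear_regression <- function(outcome, predictor, conf_level = 0.90) {
  ok <- !is.na(outcome) & !is.na(predictor)
  outcome <- outcome[ok]
  predictor <- predictor[ok]
  if (length(outcome) < 3L) stop("need at least 3 complete observations")
  if (stats::var(predictor) == 0) stop("constant predictor")
  fit <- stats::lm(outcome ~ predictor)
  co <- summary(fit)$coefficients
  ci <- stats::confint(fit, "predictor", level = conf_level)
  list(slope = co["predictor", "Estimate"],
       se = co["predictor", "Std. Error"],
       p_value = co["predictor", "Pr(>|t|)"],
       ci = as.numeric(ci),
       conf_level = conf_level,
       intercept = co["(Intercept)", "Estimate"],
       n = length(outcome),
       fit = fit)
}

#' Crossed random-intercept mixed model with ICCs and pseudo-R-squared
#'
#' Fits a (generalized) linear mixed model with random intercepts for
#' participants and stimuli, delegating the numerics to lme4. Gaussian
#' outcomes use `lmer` (REML off, maximum likelihood); binary outcomes may
#' use `binomial_logit` (`glmer`) or a linear-probability `gaussian` fit.
#' ICCs are variance shares (logit models use pi^2/3 as the residual
#' variance); pseudo-R-squared is the variance-partition kind: marginal =
#' fixed-effect variance over total, conditional adds the random-intercept
#' variances.
#'
#' @param data Trial-level data.frame.
#' @param outcome Name of the outcome column.
#' @param fixed_terms Character vector of fixed-effect terms (may include
#'   interactions like `"mds_mean:calibration_rating"`); `"1"` for an
#'   intercept-only model.
#' @param random_intercepts Character vector of grouping columns (default
#'   participants and stimuli).
#' @param family `"gaussian"` or `"binomial_logit"`.
#' @param standardize Standardize the outcome (gaussian only) and numeric
#'   predictors before fitting, giving standardized coefficients.
#' @return A `mixed_model_result`: `fixed_effects` (data.frame: term,
#'   estimate, se, p), `random_intercept_sds`, `iccs`, `pseudo_r2`
#'   (marginal, conditional), `family`, `converged`, `n_obs`, `fit`.
#' @export
fit_mixed_model <- function(data, outcome, fixed_terms,
                            random_intercepts = c("participant_id", "item_id"),
                            family = c("gaussian", "binomial_logit"),
                            standardize = FALSE) {
  family <- match.arg(family)
  miss <- setdiff(random_intercepts, names(data))
  if (length(miss) > 0L) {
    stop(sprintf("missing grouping column(s): %s", paste(miss, collapse = ", ")))
  }
  vars_needed <- unique(c(outcome, unlist(strsplit(fixed_terms, "[:*]"))))
  vars_needed <- setdiff(trimws(vars_needed), "1")
  data <- data[stats::complete.cases(data[, c(vars_needed, random_intercepts)]), ]
  if (standardize) {
    for (v in vars_needed) {
      if (is.numeric(data[[v]]) &&
          !(family == "binomial_logit" && v == outcome)) {
        data[[v]] <- as.numeric(scale(data[[v]]))
      }
    }
  }
  rhs <- paste(c(fixed_terms,
                 sprintf("(1 | %s)", random_intercepts)), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- if (family == "gaussian") {
    lme4::lmer(form, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           check.nobs.vs.rankZ = "ignore"))
  } else {
    lme4::glmer(form, data = data, family = stats::binomial(),
                nAGQ = 0L,
                control = lme4::glmerControl(calc.derivs = FALSE))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || length(msgs) == 0L

  co <- stats::coef(summary(fit))
  # Wald p-values; lmer does not print them, compute from z
  zcol <- if ("z value" %in% colnames(co)) "z value" else "t value"
  pvals <- 2 * stats::pnorm(abs(co[, zcol]), lower.tail = FALSE)
  fixed <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      p = pvals, row.names = NULL,
                      stringsAsFactors = FALSE)

  vc <- lme4::VarCorr(fit)
  re_var <- vapply(random_intercepts, function(g) as.numeric(vc[[g]]), numeric(1))
  resid_var <- if (family == "gaussian") attr(vc, "sc")^2 else pi^2 / 3
  var_fixed <- stats::var(as.numeric(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  total <- var_fixed + sum(re_var) + resid_var
  structure(
    list(fixed_effects = fixed,
         random_intercept_sds = sqrt(re_var),
         iccs = re_var / total,
         pseudo_r2 = c(marginal = var_fixed / total,
                       conditional = (var_fixed + sum(re_var)) / total),
         family = family, converged = converged,
         n_obs = nrow(data), fit = fit),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("mixed model (%s), %d obs%s\n", x$family, x$n_obs,
              if (x$converged) "" else " [did not converge]"))
  print(x$fixed_effects, digits = 3)
  cat("random-intercept SDs:",
      paste(sprintf("%s %.3f (ICC %.3f)", names(x$random_intercept_sds),
                    x$random_intercept_sds, x$iccs), collapse = ", "), "\n")
  cat(sprintf("pseudo-R2 marginal %.3f / conditional %.3f\n",
              x$pseudo_r2["marginal"], x$pseudo_r2["conditional"]))
  invisible(x)
}

#' Decision-rule configuration for the analysis pipeline
#'
#' Preregistered defaults: TOST alpha 0.1 (80% CI), equivalence bounds for
#' criterion comparisons at Cohen's d = 0.2 times the pooled SD, for
#' state-distrust comparisons at d = 0.8 times the pooled SD, SDT extreme-rate
#' policy `half_count`.
#'
#' @param alpha TOST alpha.
#' @param d_bound_criterion Equivalence half-width for criterion comparisons,
#'   in pooled-SD units.
#' @param d_bound_distrust Equivalence half-width for distrust comparisons,
#'   in pooled-SD units.
#' @param sdt_policy Extreme-rate policy for [sdt_indices()].
#' @param mixed_models Fit the exploratory mixed models (set `FALSE` to skip
#'   the slowest stage).
#' @param recognition_family Family for the recognition mixed model.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.1, d_bound_criterion = 0.2,
                            d_bound_distrust = 0.8,
                            sdt_policy = "half_count",
                            mixed_models = TRUE,
                            recognition_family = "binomial_logit") {
  structure(as.list(environment()), class = "pipeline_config")
}

# Per-participant, per-test SDT indices from the trial table.
participant_sdt <- function(trials, policy = "half_count") {
  key <- interaction(trials$participant_id, trials$test_index, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(ix) {
    sub <- trials[ix, , drop = FALSE]
    idx <- sdt_indices(count_outcomes(sub), policy)
    data.frame(participant_id = sub$participant_id[1L],
               condition = sub$condition[1L],
               test_index = sub$test_index[1L],
               hit_rate = idx$hit_rate, fa_rate = idx$fa_rate,
               d_prime = idx$d_prime, criterion_c = idx$criterion_c,
               beta = idx$beta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$test_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

rms_sd <- function(sd_a, sd_b) sqrt((sd_a^2 + sd_b^2) / 2)

# Pairwise minimal-effect / equivalence comparison on a participant-level
# outcome; the difference is taken in the direction expected to be positive.
pairwise_tost <- function(df, outcome, cond_a, cond_b, d_bound, alpha) {
  a <- df[[outcome]][df$condition == cond_a]
  b <- df[[outcome]][df$condition == cond_b]
  bound <- d_bound * rms_sd(stats::sd(a, na.rm = TRUE), stats::sd(b, na.rm = TRUE))
  welch_tost(a, b, bound = bound, alpha = alpha)
}

#' Run the full analysis pipeline on a simulated or loaded dataset
#'
#' Executes, in order: exclusions; per-participant SDT indices for both
#' tests; manipulation-check ANOVAs, equivalence tests and dominance
#' percentages on the state-distrust items; criterion ANOVAs (c and beta,
#' test 2) with pairwise minimal-effect/equivalence decisions; regressions of
#' test-2 criterion on the state-distrust items; and (optionally) the
#' exploratory crossed random-intercept mixed models of recollection, belief
#' and recognition on condition.
#'
#' @param participants Participant-level table (schema of
#'   [simulate_experiment()]).
#' @param trials Trial-level table.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(participants, trials, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_tables(participants, trials)

  excl <- apply_exclusions(participants)
  kept <- excl$participants
  trials <- trials[trials$participant_id %in% kept$participant_id, , drop = FALSE]

  sdt <- participant_sdt(trials, config$sdt_policy)
  sdt2 <- sdt[sdt$test_index == 2L, , drop = FALSE]
  pmerge <- merge(kept, sdt2[, c("participant_id", "criterion_c", "beta")],
                  by = "participant_id")

  manipulation <- list(
    commission = list(
      anova = oneway_anova_eta2(kept$state_distrust_commission, kept$condition),
      tost = pairwise_tost(kept, "state_distrust_commission",
                           "commission", "control",
                           config$d_bound_distrust, config$alpha),
      dominance = dominance_percentages(
        kept$state_distrust_commission[kept$condition == "commission"],
        kept$state_distrust_commission[kept$condition == "control"])
    ),
    omission = list(
      anova = oneway_anova_eta2(kept$state_distrust_omission, kept$condition),
      tost = pairwise_tost(kept, "state_distrust_omission",
                           "omission", "control",
                           config$d_bound_distrust, config$alpha),
      dominance = dominance_percentages(
        kept$state_distrust_omission[kept$condition == "omission"],
        kept$state_distrust_omission[kept$condition == "control"])
    )
  )

  criterion <- list(
    anova_c = oneway_anova_eta2(sdt2$criterion_c, sdt2$condition),
    anova_beta = oneway_anova_eta2(sdt2$beta, sdt2$condition),
    tost_commission_control = pairwise_tost(
      sdt2, "criterion_c", "commission", "control",
      config$d_bound_criterion, config$alpha),
    tost_control_omission = pairwise_tost(
      sdt2, "criterion_c", "control", "omission",
      config$d_bound_criterion, config$alpha)
  )

  regressions <- list(
    c_on_distrust_commission = fit_linear_regression(
      pmerge$criterion_c, pmerge$state_distrust_commission),
    c_on_distrust_omission = fit_linear_regression(
      pmerge$criterion_c, pmerge$state_distrust_omission)
  )

  mixed <- NULL
  if (isTRUE(config$mixed_models)) {
    t2 <- trials[trials$test_index == 2L, , drop = FALSE]
    t2$condition <- stats::relevel(factor(t2$condition), ref = "control")
    mixed <- list(
      recollection = fit_mixed_model(t2, "recollection", "condition"),
      belief = fit_mixed_model(t2, "belief", "condition"),
      recognition = fit_mixed_model(t2, "recognition", "condition",
                                    family = config$recognition_family)
    )
  }

  structure(
    list(exclusions = excl$report,
         sdt = sdt,
         manipulation_checks = manipulation,
         criterion = criterion,
         regressions = regressions,
         mixed_models = mixed,
         n_participants_analyzed = nrow(kept),
         config = config),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== analysis pipeline report ==\n")
  print(x$exclusions)
  cat("\ncriterion c ANOVA (test 2): ")
  print(x$criterion$anova_c)
  cat("condition means of c:\n")
  print(round(x$criterion$anova_c$group_means, 3))
  cat("\ncommission vs control: ")
  print(x$criterion$tost_commission_control)
  cat("control vs omission: ")
  print(x$criterion$tost_control_omission)
  invisible(x)
}
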