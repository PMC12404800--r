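#' Configuration of the simulated two-session recognition experiment
#'
#' Defaults encode the study conditions of the false-feedback design this
#' package analyzes: 210 participants per feedback condition, 80 stimuli in
#' counterbalanced old/new blocks of 20 per test, a 20% false-feedback
#' probability, criterion shifts of +0.24 (commission) and -0.31 (omission)
#' in c units, and manipulation-check / trait-scale settings matched to the
#' observed descriptive statistics (control criterion mean 0.16, SD 0.46;
#' state-distrust control means 3.96 and 4.52 on the 10-point items; trait
#' scales correlated 0.46).
#'
#' @param n_per_condition Participants per feedback condition.
#' @param d_prime_mean,d_prime_sd Population distribution of latent
#'   sensitivity d'.
#' @param baseline_c_mean,baseline_c_sd Population distribution of the
#'   latent test-1 criterion c.
#' @param shift_commission Test-2 criterion shift in the commission condition
#'   (c units, > 0: stricter).
#' @param shift_omission Test-2 criterion shift in the omission condition
#'   (c units, < 0: more liberal).
#' @param receptiveness_sd SD of the log of the per-participant receptiveness
#'   multiplier (LogNormal with mean 1) scaling the condition shift.
#' @param p_false_feedback Probability of false feedback on each eligible
#'   correctly-answered trial.
#' @param distrust_effect_commission,distrust_effect_omission Additive effect
#'   of matching feedback on the corresponding 10-point state-distrust item.
#' @param distrust_baseline_commission,distrust_baseline_omission Latent means
#'   of the two state-distrust items without feedback.
#' @param distrust_noise_sd SD of the latent state-distrust ratings.
#' @param rating_noise_sd SD of the noise added to memory strength before the
#'   graded-threshold mapping onto the 8-point recollection/belief scales.
#' @param belief_calibration Strength (latent SD units per standardized
#'   distrust-difference unit) of the metacognitive shift applied to belief
#'   ratings: higher omission distrust raises, higher commission distrust
#'   lowers belief.
#' @param item_effect_sd SD of per-stimulus memorability effects added to
#'   trial strength (0 disables stimulus heterogeneity and keeps the SDT
#'   parameter recovery exact).
#' @param trait_cor Correlation of the two latent trait-distrust factors.
#' @param trait_item_loading,trait_item_noise_sd Loading of each trait item on
#'   its latent factor and the item-level noise SD.
#' @param calibration_mean,calibration_sd Self-reported calibration-effort
#'   rating distribution (7-point scale).
#' @param p_attention_fail,p_not_serious,p_seen_before,p_distrust_feedback
#'   Marginal probabilities of the four exclusion flags.
#' @param missing_rating_rate Fraction of recollection/belief ratings set
#'   missing.
#' @param seed Integer master seed; every stage derives its own sub-seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_condition = 210L,
                       d_prime_mean = 1.4, d_prime_sd = 0.5,
                       baseline_c_mean = 0.16, baseline_c_sd = 0.46,
                       shift_commission = 0.24, shift_omission = -0.31,
                       receptiveness_sd = 0.5,
                       p_false_feedback = 0.20,
                       distrust_effect_commission = 0.55,
                       distrust_effect_omission = 0.55,
                       distrust_baseline_commission = 3.96,
                       distrust_baseline_omission = 4.52,
                       distrust_noise_sd = 2.2,
                       rating_noise_sd = 1.0,
                       belief_calibration = 0.15,
                       item_effect_sd = 0,
                       trait_cor = 0.46,
                       trait_item_loading = 1.2,
                       trait_item_noise_sd = 1.0,
                       calibration_mean = 4.48, calibration_sd = 1.76,
                       p_attention_fail = 0, p_not_serious = 0,
                       p_seen_before = 0.005, p_distrust_feedback = 0.043,
                       missing_rating_rate = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  check <- function(ok, field) {
    if (!isTRUE(ok)) stop(sprintf("invalid sim_config field: %s", field))
  }
  check(cfg$n_per_condition >= 1, "n_per_condition")
  check(cfg$d_prime_sd >= 0, "d_prime_sd")
  check(cfg$baseline_c_sd >= 0, "baseline_c_sd")
  check(cfg$receptiveness_sd >= 0, "receptiveness_sd")
  check(cfg$p_false_feedback >= 0 && cfg$p_false_feedback <= 1, "p_false_feedback")
  check(cfg$distrust_noise_sd > 0, "distrust_noise_sd")
  check(cfg$rating_noise_sd >= 0, "rating_noise_sd")
  check(cfg$item_effect_sd >= 0, "item_effect_sd")
  check(abs(cfg$trait_cor) <= 1, "trait_cor")
  check(cfg$trait_item_noise_sd > 0, "trait_item_noise_sd")
  for (f in c("p_attention_fail", "p_not_serious", "p_seen_before",
              "p_distrust_feedback", "missing_rating_rate")) {
    check(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  cfg$n_per_condition <- as.integer(cfg$n_per_condition)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Build the counterbalanced 80-item stimulus design
#'
#' Randomly splits the 80 items into two 40-item sets used as old or new
#' material, each subdivided into two 20-item sub-blocks tested in test 1 or
#' test 2. Participants cycle through four counterbalance cells so that each
#' item is an old item for half of the participants (exact for even n) and
#' every test presents exactly 20 old and 20 new items.
#'
#' @param n_participants Number of participants (even for an exact
#'   counterbalance; odd n triggers a warning).
#' @param seed Integer seed for the item permutation.
#' @param items Character vector of at least 80 item identifiers (the first
#'   80 are used).
#' @return An object of class `stimulus_design`: list with `items` and
#'   `assignment`, a data.frame (participant_id, item_id, item_status,
#'   test_index) of 80 rows per participant.
#' @export
build_design <- function(n_participants, seed = 1L,
                         items = sprintf("item_%02d", 1:80)) {
  if (length(items) < 80L) stop("need at least 80 item identifiers")
  items <- items[1:80]
  if (anyDuplicated(items)) stop("item identifiers must be unique")
  if (n_participants %% 2L != 0L) {
    warning("odd n_participants: old/new counterbalance is inexact")
  }
  perm <- withr_seed(seed, sample(items))
  sub_block <- list(A1 = perm[1:20], A2 = perm[21:40],
                    B1 = perm[41:60], B2 = perm[61:80])
  # four counterbalance cells: old set x which sub-block is tested first;
  # consecutive participants alternate the old set so any even n balances.
  cells <- list(
    list(old = c("A1", "A2"), t1_old = "A1", t1_new = "B1"),
    list(old = c("B1", "B2"), t1_old = "B1", t1_new = "A1"),
    list(old = c("A1", "A2"), t1_old = "A2", t1_new = "B2"),
    list(old = c("B1", "B2"), t1_old = "B2", t1_new = "A2")
  )
  per_participant <- lapply(seq_len(n_participants), function(p) {
    cell <- cells[[(p - 1L) %% 4L + 1L]]
    blocks <- names(sub_block)
    status <- ifelse(blocks %in% cell$old, "old", "new")
    test <- ifelse(blocks %in% c(cell$t1_old, cell$t1_new), 1L, 2L)
    data.frame(
      participant_id = p,
      item_id = unlist(sub_block, use.names = FALSE),
      item_status = rep(status, each = 20L),
      test_index = rep(test, each = 20L),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(items = items, assignment = do.call(rbind, per_participant)),
    class = "stimulus_design"
  )
}

#' Simulate one recognition test for a cohort
#'
#' Draws trial-level data from the equal-variance Gaussian SDT model: memory
#' strength is Normal(d', 1) for old items and Normal(0, 1) for new items
#' (plus an optional per-item memorability effect), and the participant
#' answers "old" when strength exceeds `latent_c + d'/2` — the criterion is
#' placed relative to the midpoint so the standard estimate of c is unbiased
#' for `latent_c`. Recollection ratings are a graded-threshold mapping of
#' strength plus noise onto 1..8 (7 cut points equally spaced over the
#' strength midpoint +/- 2.5 SD); belief ratings add a metacognitive
#' calibration shift proportional to the participant's standardized
#' omission-minus-commission state-distrust difference.
#'
#' @param participants Data.frame with columns `participant_id`, `condition`,
#'   `latent_d_prime` and `latent_c_test1`/`latent_c_test2`; optionally
#'   `state_distrust_commission`/`_omission` (needed when
#'   `belief_calibration > 0`).
#' @param design A [build_design()] result.
#' @param test_index 1 or 2.
#' @param config A [sim_config()].
#' @param seed Seed for this test's draws (defaults to a stream derived from
#'   `config$seed` and `test_index`).
#' @return Data.frame of trial records: participant_id, condition,
#'   test_index, item_id, item_status, recognition, recollection, belief,
#'   feedback (initialized to `"none"`).
#' @export
simulate_test <- function(participants, design, test_index, config,
                          seed = derive_seed(config$seed, 10L + test_index)) {
  stopifnot(inherits(design, "stimulus_design"), test_index %in% c(1L, 2L),
            inherits(config, "sim_config"))
  c_col <- paste0("latent_c_test", test_index)
  need <- c("participant_id", "condition", "latent_d_prime", c_col)
  miss <- setdiff(need, names(participants))
  if (length(miss) > 0L) {
    stop(sprintf("participants table lacks latent parameter column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  trials <- design$assignment[design$assignment$test_index == test_index &
                                design$assignment$participant_id %in%
                                  participants$participant_id, , drop = FALSE]
  idx <- match(trials$participant_id, participants$participant_id)
  d <- participants$latent_d_prime[idx]
  cc <- participants[[c_col]][idx]
  n <- nrow(trials)
  old <- trials$item_status == "old"

  withr_seed(seed, {
    item_eff <- if (config$item_effect_sd > 0) {
      eff <- stats::rnorm(length(design$items), 0, config$item_effect_sd)
      names(eff) <- design$items
      eff[trials$item_id]
    } else rep(0, n)
    strength <- stats::rnorm(n, mean = ifelse(old, d, 0), sd = 1) + item_eff
    recognition <- as.integer(strength > cc + d / 2)

    graded <- function(latent) {
      # 7 equally spaced cuts over the strength midpoint +/- 2.5 SD
      cuts <- outer(d / 2, seq(-2.5, 2.5, length.out = 7), `+`)
      1L + rowSums(latent > cuts)
    }
    recollection <- graded(strength + stats::rnorm(n, 0, config$rating_noise_sd))
    belief_shift <- rep(0, n)
    if (config$belief_calibration != 0) {
      if (!all(c("state_distrust_commission", "state_distrust_omission") %in%
                 names(participants))) {
        stop("belief_calibration > 0 needs state-distrust columns in participants")
      }
      dz <- (participants$state_distrust_omission[idx] -
               participants$state_distrust_commission[idx]) /
        config$distrust_noise_sd
      belief_shift <- config$belief_calibration * dz
    }
    belief <- graded(strength + belief_shift +
                       stats::rnorm(n, 0, config$rating_noise_sd))
    if (config$missing_rating_rate > 0) {
      recollection[stats::runif(n) < config$missing_rating_rate] <- NA_integer_
      belief[stats::runif(n) < config$missing_rating_rate] <- NA_integer_
    }
    data.frame(
      participant_id = trials$participant_id,
      condition = participants$condition[idx],
      test_index = test_index,
      item_id = trials$item_id,
      item_status = trials$item_status,
      recognition = recognition,
      recollection = recollection,
      belief = belief,
      feedback = "none",
      stringsAsFactors = FALSE
    )
  })
}

#' Apply the trial-level false-feedback rule
#'
#' Commission condition: each correctly recognized old item (old, "yes")
#' receives false feedback `false_new` with probability `p`, otherwise no
#' feedback; each false alarm (new, "yes") receives true feedback `true_new`;
#' misses and correct rejections receive none. Omission condition: each
#' correct rejection (new, "no") receives `false_old` with probability `p`;
#' each miss (old, "no") receives `true_old`; "yes" responses receive none.
#' Control: no feedback at all.
#'
#' @param trials Trial data.frame (one participant or many; the rule is
#'   trial-wise) with `item_status` and `recognition`.
#' @param condition `"commission"`, `"omission"` or `"control"`.
#' @param p_false_feedback Probability of false feedback on eligible trials.
#' @param seed Integer seed.
#' @return `trials` with its `feedback` column filled in.
#' @export
apply_feedback <- function(trials, condition, p_false_feedback = 0.20,
                           seed = 1L) {
  if (!condition %in% c("commission", "omission", "control")) {
    stop(sprintf("unknown condition %s", dQuote(condition)))
  }
  stopifnot(p_false_feedback >= 0, p_false_feedback <= 1)
  n <- nrow(trials)
  feedback <- rep("none", n)
  old <- trials$item_status == "old"
  yes <- trials$recognition == 1L
  if (condition == "commission") {
    eligible <- old & yes
    u <- withr_seed(seed, stats::runif(n))
    feedback[eligible & u < p_false_feedback] <- "false_new"
    feedback[!old & yes] <- "true_new"
  } else if (condition == "omission") {
    eligible <- !old & !yes
    u <- withr_seed(seed, stats::runif(n))
    feedback[eligible & u < p_false_feedback] <- "false_old"
    feedback[old & !yes] <- "true_old"
  }
  trials$feedback <- feedback
  trials
}

# Draw trait-scale item responses from a bivariate latent factor model.
# Returns mds (n x 20, 1..7), ssmq (n x 18, -4..4, raw i.e. NOT reversed),
# and the latent factors.
simulate_trait_items <- function(n, config, seed) {
  withr_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- config$trait_cor * z1 + sqrt(1 - config$trait_cor^2) * stats::rnorm(n)
    lam <- config$trait_item_loading
    nz <- config$trait_item_noise_sd
    mds <- vapply(1:20, function(i) {
      clip_rating(4 + lam * z1 + stats::rnorm(n, 0, nz), 1, 7)
    }, numeric(n))
    # raw SSMQ is a memory-confidence scale: higher omission distrust ->
    # lower raw score; reversal happens at scoring time
    ssmq <- vapply(1:18, function(i) {
      clip_rating(-lam * z2 + stats::rnorm(n, 0, nz), -4, 4)
    }, numeric(n))
    if (n == 1L) {
      mds <- matrix(mds, nrow = 1L)
      ssmq <- matrix(ssmq, nrow = 1L)
    }
    colnames(mds) <- sprintf("mds_%02d", 1:20)
    colnames(ssmq) <- sprintf("ssmq_%02d", 1:18)
    list(mds = mds, ssmq = ssmq, latent_commission = z1, latent_omission = z2)
  })
}

#' Simulate the full two-session false-feedback experiment
#'
#' Generates a complete synthetic dataset with the structure of the
#' two-session design: balanced assignment to the three feedback conditions
#' and the two manipulation-check orders, latent SDT parameters per
#' participant, counterbalanced 80-item stimulus design, test 1, trial-level
#' feedback, a condition-dependent test-2 criterion shift scaled by a
#' LogNormal receptiveness multiplier, test 2, 10-point state-distrust items
#' (latent-continuous, then rounded and clipped), trait-scale item responses,
#' a 7-point calibration-effort rating, exclusion flags, and a top-10%
#' accuracy flag computed within condition from test 2 only.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_experiment` with elements `participants`
#'   (one row per participant), `trials` (one row per trial, both tests,
#'   feedback labels filled for test 1), `trait_items` (item-level trait
#'   responses), and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_cond <- config$n_per_condition
  n <- 3L * n_cond
  conditions <- rep(c("commission", "control", "omission"), times = n_cond)
  mc_order <- rep_len(c("before_test2", "after_test2"), n)

  lat <- withr_seed(derive_seed(config$seed, 1L), {
    d_prime <- pmax(0.1, stats::rnorm(n, config$d_prime_mean, config$d_prime_sd))
    c1 <- stats::rnorm(n, config$baseline_c_mean, config$baseline_c_sd)
    recept <- stats::rlnorm(n, meanlog = -config$receptiveness_sd^2 / 2,
                            sdlog = config$receptiveness_sd)
    list(d_prime = d_prime, c1 = c1, recept = recept)
  })
  shift <- ifelse(conditions == "commission", config$shift_commission,
                  ifelse(conditions == "omission", config$shift_omission, 0))
  c2 <- lat$c1 + shift * lat$recept

  distrust <- withr_seed(derive_seed(config$seed, 2L), {
    dc <- config$distrust_baseline_commission +
      ifelse(conditions == "commission", config$distrust_effect_commission, 0) +
      stats::rnorm(n, 0, config$distrust_noise_sd)
    do <- config$distrust_baseline_omission +
      ifelse(conditions == "omission", config$distrust_effect_omission, 0) +
      stats::rnorm(n, 0, config$distrust_noise_sd)
    list(commission = clip_rating(dc, 1, 10), omission = clip_rating(do, 1, 10))
  })

  traits <- simulate_trait_items(n, config, derive_seed(config$seed, 3L))

  misc <- withr_seed(derive_seed(config$seed, 4L), {
    list(
      calibration = clip_rating(
        stats::rnorm(n, config$calibration_mean, config$calibration_sd), 1, 7),
      attention_fail = as.integer(stats::runif(n) < config$p_attention_fail),
      not_serious = as.integer(stats::runif(n) < config$p_not_serious),
      seen_before = as.integer(stats::runif(n) < config$p_seen_before),
      distrusted_feedback = as.integer(stats::runif(n) < config$p_distrust_feedback)
    )
  })

  participants <- data.frame(
    participant_id = seq_len(n),
    condition = conditions,
    mc_order = mc_order,
    latent_d_prime = lat$d_prime,
    latent_c_test1 = lat$c1,
    latent_c_test2 = c2,
    receptiveness = lat$recept,
    state_distrust_commission = distrust$commission,
    state_distrust_omission = distrust$omission,
    mds_mean = rowMeans(traits$mds),
    ssmq_mean = rowMeans(-traits$ssmq),
    calibration_rating = misc$calibration,
    attention_fail = misc$attention_fail,
    not_serious = misc$not_serious,
    seen_before = misc$seen_before,
    distrusted_feedback = misc$distrusted_feedback,
    stringsAsFactors = FALSE
  )

  design <- build_design(n, seed = derive_seed(config$seed, 5L))
  trials1 <- simulate_test(participants, design, 1L, config)
  fb_seeds <- derive_seed(config$seed, 6L) + seq_len(n)
  trials1 <- do.call(rbind, lapply(split(trials1, trials1$participant_id),
    function(tr) {
      p <- tr$participant_id[1L]
      apply_feedback(tr, participants$condition[p], config$p_false_feedback,
                     seed = fb_seeds[p])
    }))
  rownames(trials1) <- NULL
  trials2 <- simulate_test(participants, design, 2L, config)
  trials <- rbind(trials1, trials2)
  trials <- trials[order(trials$participant_id, trials$test_index,
                         trials$item_id), , drop = FALSE]
  rownames(trials) <- NULL

  acc2 <- tapply(
    (trials2$recognition == 1L) == (trials2$item_status == "old"),
    trials2$participant_id, mean)
  acc2 <- acc2[as.character(participants$participant_id)]
  top <- unlist(lapply(split(seq_len(n), conditions), function(ix) {
    k <- max(1L, floor(0.10 * length(ix)))
    ix[rank(-acc2[ix], ties.method = "first") <= k]
  }), use.names = FALSE)
  participants$top_performer <- as.integer(seq_len(n) %in% top)

  structure(
    list(participants = participants, trials = trials,
         trait_items = traits[c("mds", "ssmq")], config = config),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("simulated experiment: %d participants (3 x %d), %d trials\n",
              nrow(x$participants), x$config$n_per_condition, nrow(x$trials)))
  invisible(x)
}
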