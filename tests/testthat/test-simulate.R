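test_that("stimulus design is counterbalanced with 20 old + 20 new per test", {
  des <- build_design(8, seed = 2)
  a <- des$assignment
  tallies <- aggregate(item_id ~ participant_id + test_index + item_status,
                       a, length)
  expect_true(all(tallies$item_id == 20L))
  # per participant: exactly 40 old and 40 new
  per_p <- table(a$participant_id, a$item_status)
  expect_true(all(per_p == 40L))

  # two-person counterbalance: participant 1's old set is participant 2's new set
  old1 <- sort(a$item_id[a$participant_id == 1 & a$item_status == "old"])
  new2 <- sort(a$item_id[a$participant_id == 2 & a$item_status == "new"])
  expect_identical(old1, new2)
})

test_that("each item is old for exactly half of an even cohort", {
  des <- build_design(100, seed = 3)
  a <- des$assignment
  old_counts <- table(a$item_id[a$item_status == "old"])
  expect_equal(length(old_counts), 80L)
  expect_true(all(old_counts == 50L))
  expect_warning(build_design(5), "odd")
  expect_error(build_design(4, items = sprintf("x%d", 1:79)), "80")
})

test_that("chance responders produce equal hit and false-alarm rates", {
  cfg <- sim_config(n_per_condition = 2, d_prime_mean = 0, d_prime_sd = 0,
                    baseline_c_mean = 0, baseline_c_sd = 0,
                    belief_calibration = 0, seed = 4)
  n <- 300
  participants <- data.frame(
    participant_id = seq_len(n), condition = "control",
    latent_d_prime = 0, latent_c_test1 = 0
  )
  des <- build_design(n, seed = 5)
  tr <- simulate_test(participants, des, 1L, cfg, seed = 6)
  ct <- count_outcomes(tr)
  ph <- ct$hits / ct$n_old
  pf <- ct$false_alarms / ct$n_new
  se <- sqrt(0.5 * 0.5 * (1 / ct$n_old + 1 / ct$n_new))
  expect_lt(abs(ph - pf), 3 * se)
})

test_that("noise-free recollection is a deterministic step function of strength", {
  cfg <- sim_config(n_per_condition = 2, rating_noise_sd = 0,
                    belief_calibration = 0, seed = 8)
  participants <- data.frame(
    participant_id = 1:4, condition = "control",
    latent_d_prime = 1.4, latent_c_test1 = 0.16,
    latent_c_test2 = 0.16
  )
  des <- build_design(4, seed = 9)
  tr <- simulate_test(participants, des, 1L, cfg, seed = 10)
  tr2 <- simulate_test(participants, des, 1L, cfg, seed = 10)
  expect_identical(tr, tr2)  # same seed, same draws
  # recollection and belief coincide when both are noise-free and uncalibrated
  expect_identical(tr$recollection, tr$belief)
  # brute-force threshold oracle: recover strength bin from the rating scale
  cuts <- 1.4 / 2 + seq(-2.5, 2.5, length.out = 7)
  expect_true(all(tr$recollection >= 1 & tr$recollection <= 8))
  # a "yes" at criterion c + d'/2 = 0.86 implies strength > 0.86, hence a
  # rating of at least 1 + sum(0.86 > cuts) is common; check consistency:
  # ratings equal the deterministic mapping of some strength that also
  # produced the recognition response
  thresh <- 0.16 + 1.4 / 2
  yes <- tr$recognition == 1L
  min_rating_if_yes <- 1L + sum(thresh > cuts)
  expect_true(all(tr$recollection[yes] >= min_rating_if_yes))
})

test_that("SDT parameters are recovered from 1e5 simulated trials", {
  # homogeneous cohort: pooled counts estimate the generating d' and c
  cfg <- sim_config(n_per_condition = 2, rating_noise_sd = 1,
                    belief_calibration = 0, seed = 15)
  n <- 2500  # x 40 trials per test = 1e5 trials
  participants <- data.frame(
    participant_id = seq_len(n), condition = "control",
    latent_d_prime = 1.4, latent_c_test1 = 0.16
  )
  des <- build_design(n, seed = 16)
  tr <- simulate_test(participants, des, 1L, cfg, seed = 17)
  expect_equal(nrow(tr), 100000L)
  ct <- count_outcomes(tr)
  est <- sdt_indices(ct)
  h_true <- pnorm(1.4 / 2 - 0.16)
  f_true <- pnorm(-1.4 / 2 - 0.16)
  se_h <- sqrt(h_true * (1 - h_true) / ct$n_old)
  se_f <- sqrt(f_true * (1 - f_true) / ct$n_new)
  # delta-method SEs for d' and c from binomial rate errors
  se_d <- sqrt((se_h / dnorm(qnorm(h_true)))^2 + (se_f / dnorm(qnorm(f_true)))^2)
  expect_lt(abs(est$d_prime - 1.4), 3 * se_d)
  expect_lt(abs(est$criterion_c - 0.16), 3 * se_d / 2)
})

test_that("feedback rules label exactly the eligible trials", {
  tr <- random_trials(seed = 41)
  ctl <- apply_feedback(tr, "control", 0.2, seed = 1)
  expect_true(all(ctl$feedback == "none"))

  com0 <- apply_feedback(tr, "commission", 0, seed = 1)
  expect_true(all(com0$feedback[com0$item_status == "new" &
                                  com0$recognition == 1] == "true_new"))
  expect_true(all(com0$feedback[!(com0$item_status == "new" &
                                    com0$recognition == 1)] == "none"))

  com <- apply_feedback(tr, "commission", 0.5, seed = 2)
  # conservation: no feedback ever on "no" responses in commission
  expect_true(all(com$feedback[com$recognition == 0] == "none"))
  expect_true(all(com$feedback[com$item_status == "old" & com$recognition == 1]
                  %in% c("none", "false_new")))

  om <- apply_feedback(tr, "omission", 0.5, seed = 2)
  expect_true(all(om$feedback[om$recognition == 1] == "none"))
  expect_true(all(om$feedback[om$item_status == "old" & om$recognition == 0]
                  == "true_old"))
  expect_true(all(om$feedback[om$item_status == "new" & om$recognition == 0]
                  %in% c("none", "false_old")))

  expect_error(apply_feedback(tr, "placebo"), "unknown condition")
})

test_that("false-feedback fraction among eligible trials converges to p", {
  # binomial oracle: 1e4 eligible correct-old trials at p = 0.2
  n <- 10000L
  tr <- data.frame(
    participant_id = 1L, condition = "commission", test_index = 1L,
    item_id = sprintf("i%05d", 1:n), item_status = "old",
    recognition = 1L, recollection = 5L, belief = 5L, feedback = "none",
    stringsAsFactors = FALSE
  )
  fb <- apply_feedback(tr, "commission", 0.2, seed = 33)
  frac <- mean(fb$feedback == "false_new")
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("simulate_experiment bookkeeping, determinism and counterbalance", {
  cfg <- sim_config(n_per_condition = 10, seed = 7)
  exp1 <- simulate_experiment(cfg)
  expect_equal(nrow(exp1$participants), 30L)
  expect_equal(nrow(exp1$trials), 30L * 80L)
  expect_equal(as.vector(table(exp1$participants$condition)), rep(10L, 3))
  expect_equal(as.vector(table(exp1$participants$mc_order,
                               exp1$participants$condition)["before_test2", ]),
               rep(5L, 3))
  # determinism: identical config -> byte-identical CSV output
  d1 <- tempfile(); d2 <- tempfile()
  write_tables(exp1, d1)
  write_tables(simulate_experiment(cfg), d2)
  for (f in c("participants.csv", "trials.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # counterbalance: each item old for n/2 participants
  old_counts <- table(exp1$trials$item_id[exp1$trials$item_status == "old"])
  expect_true(all(old_counts == 15L))
  # feedback only on test 1, and only in feedback conditions
  t2 <- exp1$trials[exp1$trials$test_index == 2L, ]
  expect_true(all(t2$feedback == "none"))
  ctl_ids <- exp1$participants$participant_id[exp1$participants$condition == "control"]
  expect_true(all(exp1$trials$feedback[exp1$trials$participant_id %in% ctl_ids]
                  == "none"))
})

test_that("top-performer flag marks the top 10% by test-2 accuracy per condition", {
  exp <- small_experiment()
  p <- exp$participants
  t2 <- exp$trials[exp$trials$test_index == 2L, ]
  acc <- tapply((t2$recognition == 1L) == (t2$item_status == "old"),
                t2$participant_id, mean)
  for (cond in unique(p$condition)) {
    ids <- p$participant_id[p$condition == cond]
    k <- max(1L, floor(0.10 * length(ids)))
    expect_equal(sum(p$top_performer[p$condition == cond]), k)
    flagged <- p$participant_id[p$condition == cond & p$top_performer == 1L]
    expect_true(min(acc[as.character(flagged)]) >=
                  sort(acc[as.character(ids)], decreasing = TRUE)[k])
  }
})

test_that("null configuration produces no condition differences", {
  cfg <- sim_config(n_per_condition = 60, shift_commission = 0,
                    shift_omission = 0, distrust_effect_commission = 0,
                    distrust_effect_omission = 0, belief_calibration = 0,
                    seed = 23)
  exp <- simulate_experiment(cfg)
  # latent criteria are exchangeable across conditions under the null
  av <- oneway_anova_eta2(exp$participants$latent_c_test2,
                          exp$participants$condition)
  expect_gt(av$p_value, 0.001)
  expect_lt(av$eta_squared, 0.05)
})

test_that("invalid sim_config fields are rejected by name", {
  expect_error(sim_config(p_false_feedback = 1.5), "p_false_feedback")
  expect_error(sim_config(n_per_condition = 0), "n_per_condition")
  expect_error(sim_config(missing_rating_rate = -0.1), "missing_rating_rate")
})
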