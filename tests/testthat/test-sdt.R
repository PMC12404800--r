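test_that("count_outcomes tabulates hits, misses, false alarms, correct rejections", {
  perfect <- data.frame(
    item_status = rep(c("old", "new"), each = 20),
    recognition = rep(c(1L, 0L), each = 20)
  )
  ct <- count_outcomes(perfect)
  expect_equal(unlist(ct[c("hits", "misses", "false_alarms", "correct_rejections")]),
               c(hits = 20L, misses = 0L, false_alarms = 0L, correct_rejections = 20L))

  mixed <- data.frame(
    item_status = rep(c("old", "new"), each = 20),
    recognition = c(rep(1L, 16), rep(0L, 4), rep(1L, 6), rep(0L, 14))
  )
  ct <- count_outcomes(mixed)
  expect_equal(c(ct$hits, ct$misses, ct$false_alarms, ct$correct_rejections),
               c(16L, 4L, 6L, 14L))
})

test_that("count_outcomes matches a brute-force loop on random tables", {
  for (seed in 1:5) {
    tr <- random_trials(seed = seed)
    ct <- count_outcomes(tr)
    tally <- c(0L, 0L, 0L, 0L)  # H, M, FA, CR
    for (i in seq_len(nrow(tr))) {
      old <- tr$item_status[i] == "old"
      yes <- tr$recognition[i] == 1L
      j <- if (old && yes) 1L else if (old) 2L else if (yes) 3L else 4L
      tally[j] <- tally[j] + 1L
    }
    expect_equal(c(ct$hits, ct$misses, ct$false_alarms, ct$correct_rejections),
                 tally)
  }
})

test_that("count_outcomes rejects unknown codes naming the trial", {
  tr <- random_trials()
  tr$item_status[3] <- "maybe"
  expect_error(count_outcomes(tr), "row 3")
  tr <- random_trials()
  tr$recognition[7] <- 2L
  expect_error(count_outcomes(tr), "row 7")
})

test_that("adjust_rates applies each extreme-rate policy correctly", {
  perfect <- recognition_counts(20, 0, 0, 20)
  expect_equal(adjust_rates(perfect, "half_count"),
               c(hit_rate = 0.975, fa_rate = 0.025))
  mid <- recognition_counts(16, 4, 6, 14)
  expect_equal(adjust_rates(mid, "half_count"), c(hit_rate = 0.8, fa_rate = 0.3))
  expect_equal(adjust_rates(mid, "none"), c(hit_rate = 0.8, fa_rate = 0.3))
  expect_equal(adjust_rates(mid, "log_linear"),
               c(hit_rate = 16.5 / 21, fa_rate = 6.5 / 21))
  degenerate <- recognition_counts(20, 0, 20, 0)
  expect_error(adjust_rates(degenerate, "none"), "undefined")
  r <- adjust_rates(degenerate, "log_linear")
  expect_true(all(r > 0 & r < 1))
})

test_that("sdt_indices reproduces hand-computed equal-variance SDT values", {
  sym <- sdt_from_rates(0.8, 0.2)
  expect_equal(sym$criterion_c, 0, tolerance = 1e-12)
  expect_equal(sym$beta, 1, tolerance = 1e-12)

  s <- sdt_from_rates(0.8, 0.3)
  expect_equal(s$d_prime, qnorm(0.8) - qnorm(0.3), tolerance = 1e-12)
  expect_lt(abs(s$d_prime - 1.366), 1e-3)
  expect_lt(abs(s$criterion_c - (-0.159)), 1e-3)
  expect_lt(abs(s$beta - 0.805), 1e-3)

  chance <- sdt_from_rates(0.5, 0.5)
  expect_equal(chance$d_prime, 0)
  expect_equal(chance$criterion_c, 0)
  expect_equal(chance$beta, 1)
})

test_that("beta = exp(c * d') identity and antisymmetry hold for random counts", {
  set.seed(11)
  for (i in 1:50) {
    h <- sample(0:20, 1)
    f <- sample(0:20, 1)
    s <- sdt_indices(recognition_counts(h, 20 - h, f, 20 - f))
    expect_lt(abs(s$beta - exp(s$criterion_c * s$d_prime)), 1e-10)
    # swapping H <-> 1-F negates c and preserves d'
    sw <- sdt_from_rates(1 - s$fa_rate, 1 - s$hit_rate)
    expect_equal(sw$criterion_c, -s$criterion_c, tolerance = 1e-12)
    expect_equal(sw$d_prime, s$d_prime, tolerance = 1e-12)
  }
})

test_that("with F fixed, increasing H raises d' and lowers c", {
  f <- 0.3
  hs <- seq(0.35, 0.95, by = 0.05)
  res <- lapply(hs, function(h) sdt_from_rates(h, f))
  d <- vapply(res, `[[`, numeric(1), "d_prime")
  cc <- vapply(res, `[[`, numeric(1), "criterion_c")
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(cc) < 0))
})

test_that("cohens_d pools as requested and rejects bad SDs", {
  expect_equal(cohens_d(0.06, 0.30, 0, 0.30)$cohens_d, 0.2)
  expect_equal(cohens_d(1, 1, 1, 2)$cohens_d, 0)
  expect_equal(cohens_d(1.0, 1.0, 0.5, 1.0)$cohens_d, 0.5)
  expect_equal(cohens_d(1, 2, 0, 1, n_a = 10, n_b = 30,
                        pooling = "n_weighted")$pooled_sd,
               sqrt((9 * 4 + 29 * 1) / 38))
  expect_error(cohens_d(1, 0, 0, 1), "positive")
  expect_error(cohens_d(1, 1, 0, 1, pooling = "n_weighted"), "n_a")
})

test_that("probability of superiority is Phi(d/sqrt(2)) and matches Monte Carlo", {
  expect_equal(probability_of_superiority(0), 0.5)
  expect_equal(round(100 * probability_of_superiority(1), 1), 76.0)
  expect_equal(probability_of_superiority(0.5), pnorm(0.5 / sqrt(2)))
  # Monte-Carlo cross-check at d = 0.8
  set.seed(21)
  n <- 1e6
  p_mc <- mean(rnorm(n, 0.8) > rnorm(n))
  se <- sqrt(p_mc * (1 - p_mc) / n)
  expect_lt(abs(probability_of_superiority(0.8) - p_mc), 3 * se)
  # monotone in d
  d_grid <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(probability_of_superiority(d_grid)) > 0))
})

test_that("dominance percentages classify all cross-group pairs", {
  expect_equal(dominance_percentages(c(2, 3), c(1, 2)),
               c(pct_a_greater = 75, pct_b_greater = 0, pct_tied = 25))
  expect_equal(dominance_percentages(c(4, 4), c(4, 4)),
               c(pct_a_greater = 0, pct_b_greater = 0, pct_tied = 100))
  expect_equal(dominance_percentages(1, 2),
               c(pct_a_greater = 0, pct_b_greater = 100, pct_tied = 0))
  expect_error(dominance_percentages(numeric(0), 1), "non-empty")

  # brute-force double loop oracle on random instances
  set.seed(31)
  for (i in 1:5) {
    a <- sample(1:10, sample(5:60, 1), replace = TRUE)
    b <- sample(1:10, sample(5:60, 1), replace = TRUE)
    gt <- 0L; lt <- 0L; eq <- 0L
    for (x in a) for (y in b) {
      if (x > y) gt <- gt + 1L else if (x < y) lt <- lt + 1L else eq <- eq + 1L
    }
    tot <- length(a) * length(b)
    got <- dominance_percentages(a, b)
    expect_equal(unname(got),
                 100 * c(gt, lt, eq) / tot, tolerance = 1e-12)
    expect_equal(sum(got), 100)
  }
})
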