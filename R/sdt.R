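#' Tabulate recognition outcomes for one participant and test
#'
#' Counts hits, misses, false alarms and correct rejections from trial-level
#' old/new recognition data. The input is expected to be filtered to a single
#' participant and a single test; `test_index` selects the test from the
#' `test_index` column when present.
#'
#' @param trials A data.frame with columns `item_status` (`"old"`/`"new"`) and
#'   `recognition` (1 = "yes, old", 0 = "no, new"); optionally `test_index`.
#' @param test_index Integer test to tabulate (ignored when the column is
#'   absent).
#' @return An object of class `recognition_counts`: a list with integer fields
#'   `hits`, `misses`, `false_alarms`, `correct_rejections`, `n_old`, `n_new`.
#' @examples
#' trials <- data.frame(
#'   item_status = rep(c("old", "new"), each = 4),
#'   recognition = c(1, 1, 1, 0, 1, 0, 0, 0)
#' )
#' count_outcomes(trials)
#' @export
count_outcomes <- function(trials, test_index = NULL) {
  stopifnot(is.data.frame(trials))
  if (!is.null(test_index) && "test_index" %in% names(trials)) {
    trials <- trials[trials$test_index == test_index, , drop = FALSE]
  }
  if (nrow(trials) == 0L) stop("no trials to tabulate")
  status <- as.character(trials$item_status)
  resp <- trials$recognition
  bad_status <- which(!status %in% c("old", "new"))
  if (length(bad_status) > 0L) {
    stop(sprintf("unknown item_status %s in trial row %d",
                 dQuote(status[bad_status[1L]]), bad_status[1L]))
  }
  bad_resp <- which(!resp %in% c(0L, 1L))
  if (length(bad_resp) > 0L) {
    stop(sprintf("unknown recognition code %s in trial row %d",
                 deparse(resp[bad_resp[1L]]), bad_resp[1L]))
  }
  old <- status == "old"
  yes <- resp == 1L
  recognition_counts(
    hits = sum(old & yes), misses = sum(old & !yes),
    false_alarms = sum(!old & yes), correct_rejections = sum(!old & !yes)
  )
}

#' Construct a recognition-counts object
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative integer
#'   tallies. Hits + misses must equal the number of old items presented and
#'   false alarms + correct rejections the number of new items.
#' @return An object of class `recognition_counts`.
#' @export
recognition_counts <- function(hits, misses, false_alarms, correct_rejections) {
  x <- c(hits = hits, misses = misses, false_alarms = false_alarms,
         correct_rejections = correct_rejections)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  structure(
    list(hits = as.integer(hits), misses = as.integer(misses),
         false_alarms = as.integer(false_alarms),
         correct_rejections = as.integer(correct_rejections),
         n_old = as.integer(hits + misses),
         n_new = as.integer(false_alarms + correct_rejections)),
    class = "recognition_counts"
  )
}

#' @export
print.recognition_counts <- function(x, ...) {
  cat(sprintf("recognition counts: H %d / M %d (n_old %d), FA %d / CR %d (n_new %d)\n",
              x$hits, x$misses, x$n_old, x$false_alarms, x$correct_rejections, x$n_new))
  invisible(x)
}

#' Convert counts to hit and false-alarm rates with an extreme-rate policy
#'
#' Observed proportions of 0 or 1 have undefined normal quantiles. The
#' `half_count` policy (the most common SDT convention) replaces a 0 rate with
#' 1/(2N) and a 1 rate with 1 - 1/(2N), leaving interior rates untouched. The
#' `log_linear` policy adds 0.5 to every cell (rates become (x + 0.5)/(N + 1)
#' for all inputs). Policy `none` uses raw proportions and rejects degenerate
#' rates.
#'
#' @param counts A `recognition_counts` object.
#' @param policy One of `"half_count"` (default), `"log_linear"`, `"none"`.
#' @return Named numeric vector `c(hit_rate =, fa_rate =)`, both strictly
#'   inside (0, 1) for the correcting policies.
#' @export
adjust_rates <- function(counts, policy = c("half_count", "log_linear", "none")) {
  policy <- match.arg(policy)
  stopifnot(inherits(counts, "recognition_counts"))
  if (counts$n_old == 0L || counts$n_new == 0L) {
    stop("need at least one old and one new item")
  }
  h <- counts$hits
  f <- counts$false_alarms
  n_old <- counts$n_old
  n_new <- counts$n_new
  rates <- switch(policy,
    half_count = {
      hr <- h / n_old
      fr <- f / n_new
      if (hr == 0) hr <- 1 / (2 * n_old)
      if (hr == 1) hr <- 1 - 1 / (2 * n_old)
      if (fr == 0) fr <- 1 / (2 * n_new)
      if (fr == 1) fr <- 1 - 1 / (2 * n_new)
      c(hr, fr)
    },
    log_linear = c((h + 0.5) / (n_old + 1), (f + 0.5) / (n_new + 1)),
    none = {
      hr <- h / n_old
      fr <- f / n_new
      if (hr %in% c(0, 1) || fr %in% c(0, 1)) {
        stop("rate of 0 or 1 with policy 'none': normal quantile undefined")
      }
      c(hr, fr)
    }
  )
  c(hit_rate = rates[1L], fa_rate = rates[2L])
}

#' Equal-variance signal-detection indices
#'
#' Computes sensitivity d' and the response-bias indices c and beta from
#' recognition counts under the equal-variance Gaussian model:
#' d' = z(H) - z(F), c = -(z(H) + z(F))/2, beta = exp((z(F)^2 - z(H)^2)/2),
#' where z is the standard-normal quantile. Higher c (or beta) means a more
#' conservative criterion: a greater tendency to call stimuli "new". The
#' identity beta = exp(c * d') holds exactly.
#'
#' @inheritParams adjust_rates
#' @return An object of class `sdt_indices`: list with `hit_rate`, `fa_rate`,
#'   `d_prime`, `criterion_c`, `beta`.
#' @examples
#' sdt_indices(recognition_counts(16, 4, 6, 14))
#' @export
sdt_indices <- function(counts, policy = c("half_count", "log_linear", "none")) {
  rates <- adjust_rates(counts, policy)
  sdt_from_rates(rates[["hit_rate"]], rates[["fa_rate"]])
}

#' Signal-detection indices from rates already inside (0, 1)
#'
#' @param hit_rate,fa_rate Proportions strictly inside (0, 1).
#' @return An object of class `sdt_indices`.
#' @export
sdt_from_rates <- function(hit_rate, fa_rate) {
  stopifnot(hit_rate > 0, hit_rate < 1, fa_rate > 0, fa_rate < 1)
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  structure(
    list(hit_rate = hit_rate, fa_rate = fa_rate,
         d_prime = zh - zf,
         criterion_c = -(zh + zf) / 2,
         beta = exp((zf^2 - zh^2) / 2)),
    class = "sdt_indices"
  )
}

#' @export
print.sdt_indices <- function(x, ...) {
  cat(sprintf("SDT indices: H = %.3f, F = %.3f, d' = %.3f, c = %.3f, beta = %.3f\n",
              x$hit_rate, x$fa_rate, x$d_prime, x$criterion_c, x$beta))
  invisible(x)
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference (mean_a - mean_b) / pooled SD. With
#' `equal_weight_rms` pooling (the default) the pooled SD is
#' sqrt((sd_a^2 + sd_b^2)/2); `n_weighted` uses the usual
#' (n-1)-weighted pooled SD and requires both group sizes.
#'
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group standard deviations (> 0).
#' @param n_a,n_b Group sizes (needed for `n_weighted`; each >= 2).
#' @param pooling `"equal_weight_rms"` or `"n_weighted"`.
#' @return An object of class `effect_size`: list with `raw_difference`,
#'   `pooled_sd`, `cohens_d`.
#' @examples
#' cohens_d(0.06, 0.30, 0, 0.30)  # d = 0.2
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b, n_a = NULL, n_b = NULL,
                     pooling = c("equal_weight_rms", "n_weighted")) {
  pooling <- match.arg(pooling)
  if (sd_a <= 0 || sd_b <= 0) stop("standard deviations must be positive")
  pooled <- switch(pooling,
    equal_weight_rms = sqrt((sd_a^2 + sd_b^2) / 2),
    n_weighted = {
      if (is.null(n_a) || is.null(n_b)) stop("n_weighted pooling needs n_a and n_b")
      if (n_a < 2 || n_b < 2) stop("n_weighted pooling needs n >= 2 per group")
      sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
    }
  )
  diff <- mean_a - mean_b
  structure(
    list(raw_difference = diff, pooled_sd = pooled, cohens_d = diff / pooled),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("raw difference %.4g, pooled sd %.4g, Cohen's d = %.4g\n",
              x$raw_difference, x$pooled_sd, x$cohens_d))
  invisible(x)
}

#' Probability of superiority (common-language effect size)
#'
#' For two equal-variance normal populations whose means differ by Cohen's d,
#' the probability that a random draw from the first exceeds a random draw
#' from the second is Phi(d / sqrt(2)).
#'
#' @param d Standardized mean difference.
#' @return Probability in (0, 1); 0.5 at d = 0.
#' @examples
#' probability_of_superiority(1.0)  # 0.760
#' @export
probability_of_superiority <- function(d) {
  stopifnot(is.finite(d))
  stats::pnorm(d / sqrt(2))
}

#' Dominance percentages over all cross-group rating pairs
#'
#' Classifies every pair (a, b) with a from the first group and b from the
#' second as a-higher, b-higher, or tied, and reports the three percentages.
#' This is the nonparametric "how often is a rating from group A higher"
#' summary used alongside mean comparisons of Likert manipulation checks.
#'
#' @param ratings_a,ratings_b Non-empty numeric vectors of ordinal ratings.
#' @return Named numeric vector `c(pct_a_greater =, pct_b_greater =,
#'   pct_tied =)`, summing to 100.
#' @examples
#' dominance_percentages(c(2, 3), c(1, 2))
#' @export
dominance_percentages <- function(ratings_a, ratings_b) {
  ratings_a <- ratings_a[!is.na(ratings_a)]
  ratings_b <- ratings_b[!is.na(ratings_b)]
  if (length(ratings_a) == 0L || length(ratings_b) == 0L) {
    stop("both rating groups must be non-empty")
  }
  cmp <- outer(ratings_a, ratings_b, `-`)
  n <- length(cmp)
  c(pct_a_greater = 100 * sum(cmp > 0) / n,
    pct_b_greater = 100 * sum(cmp < 0) / n,
    pct_tied = 100 * sum(cmp == 0) / n)
}
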