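# Shared fixtures, built in code at test time.

# A cohort of identical recognition counts.
homogeneous_cohort <- function(n, hits = 15L, fa = 5L, n_old = 20L, n_new = 20L) {
  replicate(n, recognition_counts(hits, n_old - hits, fa, n_new - fa),
            simplify = FALSE)
}

# A random trial table for one participant (no latent model, pure tallies).
random_trials <- function(n_old = 20L, n_new = 20L, seed = 1L) {
  set.seed(seed)
  data.frame(
    participant_id = 1L,
    condition = "control",
    test_index = 1L,
    item_id = sprintf("it%02d", seq_len(n_old + n_new)),
    item_status = rep(c("old", "new"), c(n_old, n_new)),
    recognition = rbinom(n_old + n_new, 1L, rep(c(0.7, 0.3), c(n_old, n_new))),
    recollection = sample(1:8, n_old + n_new, replace = TRUE),
    belief = sample(1:8, n_old + n_new, replace = TRUE),
    feedback = "none",
    stringsAsFactors = FALSE
  )
}

# A small complete simulated experiment shared across tests.
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_config(n_per_condition = 40L, seed = 99L))
    }
    cache
  }
})
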