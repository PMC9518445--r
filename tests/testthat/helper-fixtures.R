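# Shared fixtures, built in code and cached for the duration of the run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# A small, strongly separable recording: short but event-rich.
tiny_recording <- function(seed = 5, duration_s = 120) {
  generate_recording(cap_sim_params(duration_s = duration_s, seed = seed), 1)
}

# Windows from a tiny recording, cached per (T, seed).
tiny_windows <- function(time_steps = 2, seed = 5, duration_s = 120) {
  fixture(sprintf("w_%d_%d_%d", time_steps, seed, duration_s), function() {
    make_windows(preprocess_recording(tiny_recording(seed, duration_s)),
                 time_steps)
  })
}

# A small trained model shared by prediction/robustness tests.
tiny_model <- function() {
  fixture("tiny_model", function() {
    w <- tiny_windows(2, seed = 5, duration_s = 240)
    cap_fusion(w, cap_config(hidden = 8, time_steps = 2),
               cap_control(epochs = 12, seed = 2))
  })
}

# A model trained on 4 subjects with 2 held-out recordings, for tests that
# need out-of-subject generalization (robustness protocols).
gen_fixture <- function() {
  fixture("gen_model", function() {
    cohort <- generate_cohort(cap_sim_params(n_subjects = 6, duration_s = 600,
                                             seed = 21))
    train_w <- bind_windows(prepare_cohort(cohort[1:4], 5))
    model <- cap_fusion(train_w, cap_config(hidden = 16, time_steps = 5),
                        cap_control(epochs = 5, seed = 2))
    list(model = model, test_recs = cohort[5:6])
  })
}

# Brute-force oracles -------------------------------------------------------

auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

diversity_oracle <- function(pop) {
  z <- length(pop); L <- length(pop[[1]])
  tot <- 0
  for (mu in seq_len(z - 1)) for (th in (mu + 1):z)
    tot <- tot + sum(pop[[mu]] != pop[[th]])
  2 * tot / (z * L * (z - 1))
}

youden_oracle <- function(scores, labels) {
  # exhaustive threshold scan over all observed scores and outside points
  cand <- c(min(scores) - 1, sort(unique(scores)), max(scores) + 1)
  best <- -Inf
  for (th in cand) {
    sen <- sum(scores >= th & labels == 1) / sum(labels == 1)
    spe <- sum(scores < th & labels == 0) / sum(labels == 0)
    best <- max(best, sen + spe - 1)
  }
  best
}

mean_loo_auc <- function(config, cohort, epochs, seed) {
  mean(loo_evaluate(config, cohort,
                    cap_control(epochs = epochs, seed = seed))$per_subject$auc)
}
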