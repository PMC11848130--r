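# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# default noise-free walk with metadata
fixture_walk_clean <- function() {
  cached("walk_clean", {
    m <- trial_meta("P001", "female", 1.65, 0L, 1L, "training")
    simulate_walk(gait_params(noise_sd = 0), n_steps = 6L, meta = m)
  })
}

fixture_cycles_clean <- function() {
  cached("cycles_clean", segment_trial(fixture_walk_clean()$sequence))
}

fixture_features_clean <- function() {
  cached("features_clean", {
    sw <- fixture_walk_clean()
    compute_trial_features(sw$sequence, fixture_cycles_clean())
  })
}

# a tiny hand-built pose sequence: all landmarks stacked at simple offsets
toy_sequence <- function(n = 30, fs = 30) {
  tm <- trial_meta("T01", "male", 1.80, 1L, 2L, "validation")
  t <- seq(0, by = 1 / fs, length.out = n)
  coords <- array(0, c(n, 33, 3))
  set.seed(99)
  coords[] <- rnorm(length(coords))
  pose_sequence(t, coords, fs, meta = tm)
}

# brute-force ROC-AUC over all positive-negative pairs (ties half credit)
bruteforce_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# enumerated average precision: precision at each positive's rank
enumerated_ap <- function(ranking) {
  # ranking: 0/1 labels in descending-score order, distinct scores
  pos_at <- which(ranking == 1)
  mean(vapply(pos_at, function(r) sum(ranking[1:r]) / r, numeric(1)))
}
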