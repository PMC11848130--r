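#!/usr/bin/env Rscript
# Step 4: trial-retest reliability and the design's minimum sample size.
#
# Reliability: ICC(2,1) of first-step walking speed across each training
# participant's three walks (two-way random effects, absolute agreement,
# single measure). Sample size: the binary-prediction-model minima for an
# anticipated C-statistic of 0.8, prevalence 0.2 and 3 parameters, reported
# per criterion.

suppressPackageStartupMessages(library(tristep))

ft <- read.csv("results/features_train_trials.csv")
wide <- reshape(ft[, c("participant_id", "trial_index", "walking_speed_s1")],
                idvar = "participant_id", timevar = "trial_index",
                direction = "wide")
r <- icc(wide[, -1])
message(sprintf("ICC(2,1) of first-step walking speed: %.3f (95%% CI %.3f-%.3f; n=%d, k=%d)",
                r$icc, r$lo, r$hi, r$n, r$k))

ss <- min_sample_size(c_statistic = 0.8, phi = 0.2, n_parameters = 3)
print(ss)

jsonlite::write_json(
  list(icc_walking_speed_s1 = list(icc = r$icc, lo = r$lo, hi = r$hi,
                                   n = r$n, k = r$k),
       sample_size = list(r2_cs = ss$r2_cs,
                          n_shrinkage = ss$n_shrinkage,
                          n_optimism = ss$n_optimism,
                          n_risk = ss$n_risk,
                          n_final = ss$n_final)),
  "results/reliability_and_samplesize.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote results/reliability_and_samplesize.json")
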