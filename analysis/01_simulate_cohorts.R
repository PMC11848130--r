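#!/usr/bin/env Rscript
# Step 1: simulate the two labelled gait cohorts.
#
# A training cohort of 190 participants at 12.1% fall-history prevalence and
# a validation cohort of 28 participants at 25.0% (three standing-start
# walks each, 33-landmark pose sequences at 30 fps with landmark noise of
# 0.5% of stature). Fallers carry programmed shifts on knee excursion, heel
# lift, swing-phase ratio and trunk sway. Raw trials are cached for step 02;
# a participant table and one example trial (pose CSV + sidecar + truth
# events) are written under results/.

suppressPackageStartupMessages(library(tristep))
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)

train_spec <- cohort_spec(n = 190, prevalence = 0.121, cohort = "training",
                          seed = 20260101)
valid_spec <- cohort_spec(n = 28, prevalence = 0.250, cohort = "validation",
                          seed = 20260102)

message("simulating training cohort (n = 190, 3 trials each) ...")
train <- simulate_cohort(train_spec)
message("simulating validation cohort (n = 28) ...")
valid <- simulate_cohort(valid_spec)

parts <- rbind(cbind(train$participants, cohort = "training"),
               cbind(valid$participants, cohort = "validation"))
write.csv(parts, "results/participants.csv", row.names = FALSE)

message(sprintf("training fall-history prevalence: %.1f%% (%d/%d)",
                100 * mean(train$participants$fall_history),
                sum(train$participants$fall_history), 190))
message(sprintf("validation fall-history prevalence: %.1f%% (%d/%d)",
                100 * mean(valid$participants$fall_history),
                sum(valid$participants$fall_history), 28))

# one example trial on disk in the exchange formats
ex <- train$trials[[1]]
write_pose_csv(ex$sequence, "results/example_trial.csv")
write_events_csv(cbind(ex$truth$events,
                       frame_index = round(ex$truth$events$time *
                                             ex$sequence$frame_rate)),
                 "results/example_trial_truth_events.csv")

saveRDS(train, "results/cache/train_cohort.rds")
saveRDS(valid, "results/cache/valid_cohort.rds")
message("cached cohorts under results/cache/")
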