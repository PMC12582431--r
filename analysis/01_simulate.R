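#!/usr/bin/env Rscript

# Step 1: simulate the study cohort.
#
# Generates keystroke event logs and fixation streams for a cohort of
# participants each composing one text in their first language (L1) and
# one in a second language (L2), under the default generating conditions
# (hesitation rates and durations, editing and lookback probabilities per
# text location). Writes the raw logs and the ground-truth transition
# table under results/data/.
#
# The cohort size here is 8 participants; raise `n_participants` (the
# study this emulates had 39) for a full-scale run.

suppressPackageStartupMessages(library(scribeye))

seed <- 1L
n_participants <- 8L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- session_config(n_participants = n_participants, seed = seed)
sessions <- generate_cohort(cfg)

events <- do.call(rbind, lapply(sessions, `[[`, "events"))
fixations <- do.call(rbind, lapply(sessions, `[[`, "fixations"))
truth <- do.call(rbind, lapply(sessions, function(s) s$ground_truth$transitions))

write_event_log(events, file.path(out_dir, "events.tsv"))
write_fixation_log(fixations, file.path(out_dir, "fixations.tsv"))
write.table(truth, file.path(out_dir, "ground_truth_transitions.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("Simulated %d sessions: %d events, %d fixations, %d transitions\n",
            length(sessions), nrow(events), nrow(fixations), nrow(truth)))
cat(sprintf("Ground truth plants %d lookback events (%.1f%% of writing transitions)\n",
            sum(truth$lookback, na.rm = TRUE),
            100 * mean(truth$lookback[truth$mode %in% "writing"])))
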