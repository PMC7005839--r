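#!/usr/bin/env Rscript
# Score the three addiction-like criteria for every mouse, apply the
# exclusion rule, attribute criteria against the control group's 75th
# percentiles and classify mice as addicted / non-addicted.
#
# Reads:  results/sessions.tsv (from 01_simulate_cohort.R)
# Writes: results/attribution.tsv

suppressPackageStartupMessages(library(foodaddictr))

sessions <- utils::read.delim("results/sessions.tsv",
                              stringsAsFactors = FALSE)
mice <- unique(sessions[, "mouse_id", drop = FALSE])
mice$group <- sub("_[0-9]+$", "", mice$mouse_id)
ds <- structure(list(mice = mice, sessions = sessions, logs = NULL,
                     protocol = protocol_config(
                       n_fr1 = sum(sessions$phase == "fr1") / nrow(mice),
                       n_fr5 = sum(sessions$phase == "fr5") / nrow(mice))),
                class = "protocol_dataset")

scores <- criterion_scores(ds)
exclusion <- apply_exclusion(ds)
classified <- classify_cohort(scores, exclusion, control = "control")

write_attribution_report(classified, "results/attribution.tsv")

message("Excluded: ", sum(exclusion$excluded), " of ", nrow(exclusion),
        " mice (responded < 25% of FR5 sessions and never acquired).")
message("Criterion thresholds (control 75th percentiles): persistence = ",
        round(classified$thresholds[["persistence"]], 1),
        ", motivation = ", round(classified$thresholds[["motivation"]], 1),
        ", compulsivity = ", round(classified$thresholds[["compulsivity"]], 1))
print(classified$group_summary)
message("Per-mouse report: results/attribution.tsv")
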