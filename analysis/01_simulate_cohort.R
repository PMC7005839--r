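#!/usr/bin/env Rscript
# Simulate a two-group synthetic cohort (control vs vulnerable) through the
# full phenotyping protocol and persist the event-level dataset.
#
# Writes: results/event_log.csv, results/sessions.tsv

suppressPackageStartupMessages(library(foodaddictr))

seed <- 20260924L
dir.create("results", showWarnings = FALSE)

cfg <- read_pipeline_config(system.file("extdata", "example_config.yaml",
                                        package = "foodaddictr"))
groups <- list(
  control_group(cfg$groups$control$n),
  vulnerable_group(cfg$groups$vulnerable$n)
)
protocol <- protocol_config(n_fr1 = cfg$protocol$n_fr1,
                            n_fr5 = cfg$protocol$n_fr5, seed = seed)

message("Simulating ", sum(vapply(groups, `[[`, 1L, "n")),
        " mice through ", protocol$n_fr1, " FR1 + ", protocol$n_fr5,
        " FR5 sessions + PR + shock test ...")
ds <- run_protocol(groups, protocol)

write_event_log(ds, "results/event_log.csv")
utils::write.table(ds$sessions, "results/sessions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

fr5 <- ds$sessions[ds$sessions$phase == "fr5", ]
message("Mean FR5 reinforcers/session: ",
        round(mean(fr5$reinforcers), 1),
        " (control and vulnerable pooled); ",
        nrow(ds$sessions), " session summaries written.")
message("Event log: results/event_log.csv; summaries: results/sessions.tsv")
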