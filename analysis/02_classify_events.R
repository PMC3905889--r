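#!/usr/bin/env Rscript

# Stage 2 — filter and partition the splice-event table.
#
# Reads the event table written by stage 1, applies the Bayes-factor and
# exon-length filters (BF > 10 and exon <= 500 nt regulated, split by PSI
# direction; BF < 0.1 background), and compares the recovered partition
# with the generator's planted truth.

suppressPackageStartupMessages(library(meiosplice))
SEED <- 101

events <- parse_event_table("results/events.tsv")
cls <- classify_events(events)
truth <- gen_event_table(synth_config(seed = SEED))$truth

write_event_table(cls, "results/events_classified.tsv")
tab <- table(cls$regulation)
cat("Partition of", nrow(cls), "events:\n")
print(tab)

merged <- merge(cls[, c("event_id", "regulation")], truth)
agree <- with(merged, sum(regulation == true_class))
cat("\nAgreement with planted truth:", agree, "of",
    sum(merged$true_class != "decoy"), "non-decoy events;",
    sum(merged$true_class == "decoy" & merged$regulation == "unassigned"),
    "over-length decoys correctly unassigned.\n")
cat("Classified table written to results/events_classified.tsv\n")
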