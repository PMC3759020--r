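#!/usr/bin/env Rscript
# Stage 1 — simulate the two-group verbal-fluency study.
#
# Draws one NH-like and one CI-like group (27 subjects each) from the
# shipped clustering-and-switching profiles and writes the raw long-format
# responses. Everything downstream starts from this file.

suppressPackageStartupMessages(library(fluencynet))
seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

pair <- generate_pair(seed = seed)
write_fluency(pair, file.path(out_dir, "responses.csv"))

for (ds in pair) {
  message(sprintf("group %s: %d subjects, %d distinct words, %.1f words/subject",
                  ds$group, length(ds$subjects),
                  length(unique(unlist(ds$subjects))),
                  mean(lengths(ds$subjects))))
}
message("wrote ", file.path(out_dir, "responses.csv"))
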