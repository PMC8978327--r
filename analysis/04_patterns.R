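#!/usr/bin/env Rscript
# Step 4: temporal pattern mining of circRNA trajectories. Profiles are
# normalized to the pro-B stage and binned into 3-transition sign words
# (up/down/flat per transition, 20% relative dead band).

suppressMessages({library(bcellcerna); library(readr)})
dir.create("results/patterns", showWarnings = FALSE, recursive = TRUE)

circ <- read_expression_tsv("results/data/circ_rpm.tsv", "RPM")
# pattern words are only meaningful for trajectories present in all stages
keep <- rowSums(unclass(circ)[, , drop = FALSE] > 0) == 4
mat <- unclass(circ)[keep, , drop = FALSE]
summ <- summarize_patterns(mat, delta = 0.2)

labels <- attr(summ, "labels")
write_tsv(data.frame(transcript_id = names(labels), pattern = labels),
          "results/patterns/circ_pattern_labels.tsv", progress = FALSE)
write_tsv(data.frame(pattern = names(summ), count = as.integer(summ)),
          "results/patterns/circ_pattern_counts.tsv", progress = FALSE)

cat(sprintf("classified %d all-stage circRNAs into %d observed patterns\n",
            sum(keep), length(summ)))
for (lab in c("up-up-up", "down-down-down", "down-up-down", "up-down-up")) {
  cat(sprintf("  %s: %d\n", lab,
              if (lab %in% names(summ)) summ[[lab]] else 0L))
}
cat("wrote results/patterns/\n")
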