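#!/usr/bin/env Rscript
# Step 3: adjacent-stage differential expression per layer with the
# replicate-free conditional count test (raw p < 0.05 and |log2FC| >= 1).
# Outputs one DE table per layer plus the up/down summary per comparison.

suppressMessages({library(bcellcerna); library(readr)})
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

libs <- read_tsv("results/data/library_sizes.tsv", show_col_types = FALSE)
lib_sizes <- stats::setNames(libs$library_size, libs$stage)

summ_rows <- list()
read_counts <- function(path) {
  df <- read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

for (nm in c("circ", "mirna", "mrna")) {
  counts <- read_counts(file.path("results/data", sprintf("%s_counts.tsv", nm)))
  de <- call_de_all(counts, lib_sizes)
  write_tsv(de, sprintf("results/de/%s_de.tsv", nm), progress = FALSE)
  s <- de_summary(de)
  s$layer <- nm
  summ_rows[[nm]] <- s
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%s %s: %d up, %d down\n",
                nm, s$comparison[i], s$n_up[i], s$n_down[i]))
  }
}
write_tsv(do.call(rbind, summ_rows), "results/de/de_summary.tsv",
          progress = FALSE)
cat("wrote results/de/\n")
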