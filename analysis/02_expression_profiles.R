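#!/usr/bin/env Rscript
# Step 2: expressed calls per stage, Venn (stage-specificity) classes,
# per-stage specific fractions, and inter-stage Pearson correlations for
# each omics layer. Inputs from results/data/, outputs to results/profiles/.

suppressMessages({library(bcellcerna); library(readr)})
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

layers <- list(circ = c("circ_rpm.tsv", "RPM"),
               mirna = c("mirna_tpm.tsv", "TPM"),
               mrna = c("mrna_fpkm.tsv", "FPKM"))

frac_rows <- list()
for (nm in names(layers)) {
  mat <- read_expression_tsv(file.path("results/data", layers[[nm]][1]),
                             layers[[nm]][2])
  expressed <- call_expressed(mat, threshold = 0)
  calls <- classify_specificity(expressed)
  write_tsv(calls, sprintf("results/profiles/%s_specificity_calls.tsv", nm),
            progress = FALSE)
  counts <- venn_counts(expressed)
  write_tsv(data.frame(class = names(counts), count = counts),
            sprintf("results/profiles/%s_venn_counts.tsv", nm),
            progress = FALSE)
  r <- stage_correlation(mat)
  write_tsv(data.frame(stage = rownames(r), as.data.frame(r),
                       check.names = FALSE),
            sprintf("results/profiles/%s_stage_correlation.tsv", nm),
            progress = FALSE)
  for (s in b_cell_stages()) {
    frac_rows[[length(frac_rows) + 1]] <- data.frame(
      layer = nm, stage = s,
      n_expressed = sum(expressed[, s]),
      specific_fraction = specificity_fraction(calls, s))
  }
  n_exp <- sum(calls$class != "not_expressed")
  cat(sprintf(
    "%s: %d/%d expressed somewhere; %.1f%% of those stage-specific\n",
    nm, n_exp, nrow(calls),
    100 * mean(calls$is_stage_specific[calls$class != "not_expressed"])))
}
frac <- do.call(rbind, frac_rows)
write_tsv(frac, "results/profiles/specific_fractions.tsv", progress = FALSE)
cat("wrote results/profiles/\n")
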