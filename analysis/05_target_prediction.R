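#!/usr/bin/env Rscript
# Step 5: miRNA target prediction by canonical seed matching over the
# simulated sequences (miRNA -> circRNA and miRNA -> mRNA), the bundled
# stand-in for external target databases. Externally exported interaction
# tables could be merged in at this point with merge_interactions().

suppressMessages({library(bcellcerna); library(readr)})
dir.create("results/targets", showWarnings = FALSE, recursive = TRUE)

seqs <- read_fasta("results/data/sequences.fa")
circ_ids <- read_tsv("results/data/circ_rpm.tsv", show_col_types = FALSE)[[1]]
mir_ids <- read_tsv("results/data/mirna_tpm.tsv", show_col_types = FALSE)[[1]]
mrna_ids <- read_tsv("results/data/mrna_fpkm.tsv", show_col_types = FALSE)[[1]]

mir_seqs <- seqs[names(seqs) %in% mir_ids]
circ_seqs <- seqs[names(seqs) %in% circ_ids]
mrna_seqs <- seqs[names(seqs) %in% mrna_ids]

ints <- merge_interactions(
  predict_interactions(mir_seqs, circ_seqs, "circRNA",
                       min_site_type = "7mer-A1"),
  predict_interactions(mir_seqs, mrna_seqs, "mRNA",
                       min_site_type = "7mer-A1"))
write_interactions_tsv(ints, "results/targets/interactions.tsv")

cat(sprintf("scanned %d miRNAs against %d targets: %d interactions (%d -> circRNA, %d -> mRNA)\n",
            length(mir_seqs), length(circ_seqs) + length(mrna_seqs),
            nrow(ints), sum(ints$target_kind == "circRNA"),
            sum(ints$target_kind == "mRNA")))
cat("wrote results/targets/interactions.tsv\n")
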