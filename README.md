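# bcellcerna

Stage-specific expression and circRNA–miRNA–mRNA (ceRNA) network analysis
for four-stage B-cell development transcriptomes.

During B-cell development in mouse bone marrow, cells progress through four
sorted stages — pro-B, pre-B, immature and mature. Profiling circRNAs (RPM),
miRNAs (TPM) and mRNAs (FPKM) across these stages raises a chain of
computational questions this package answers as a tested pipeline:

1. **Stage-specificity (Venn) classification** — which transcripts are
   expressed in exactly one stage? Every transcript is assigned its exact
   expressed-stage subset (15 non-empty classes + `not_expressed`); circRNAs
   are expected to be far more stage-specific than miRNAs or mRNAs.
   Inter-stage similarity is summarized by Pearson correlation of total
   expression.
2. **Adjacent-stage differential expression** — for the three transitions
   (Pre vs Pro, Immature vs Pre, Mature vs Immature), DE is called at the
   rule *raw p < 0.05 and |log2FC| ≥ 1*. Because the libraries are pooled
   (no replicates), significance comes from an exact conditional count test:
   given count *x* in library *N₁*, the count *y* in library *N₂* follows

   P(y | x) = (N₂/N₁)^y (x+y)! / ( x! y! (1+N₂/N₁)^(x+y+1) ),

   a negative binomial with size *x*+1 and success probability
   *N₁/(N₁+N₂)*; the two-sided p doubles the smaller tail and is exactly
   symmetric in the two libraries.
3. **Temporal pattern mining** — each four-stage trajectory, normalized to
   pro-B, is binned into a sign word over the three transitions
   (e.g. `down-up-down`), with a relative dead band *δ* for `flat`.
4. **Seed-match target prediction** — canonical miRNA sites on circRNA and
   mRNA sequences: `8mer`, `7mer-m8`, `7mer-A1`, `6mer`, defined from the
   reverse complement of miRNA nucleotides 2–8/2–7; a deterministic,
   self-contained stand-in for external target databases whose exports can
   be merged in.
5. **ceRNA assembly** — transcripts DE in exactly one comparison form
   exclusive groups; within a group, triplets circRNA–miRNA–mRNA are emitted
   when one miRNA has sites on both partners and directions follow the
   sponge scheme (circRNA and mRNA move together, the miRNA opposite).
   Networks are exported as SIF/GraphML.
6. **Enrichment and validation arithmetic** — hypergeometric
   over-representation (upper tail, `GeneRatio = k/n`) with
   Benjamini–Hochberg correction, and the 2^−ΔΔCt fold-change calculator
   used for qPCR-style validation.

A synthetic tri-omics generator (`generate_dataset()`) plants all of this
structure — stage-specific fractions, fold changes, sign-word patterns,
sponge triplets with real seed sites — and records it as a ground-truth
object, so every pipeline stage is validated by exact recovery tests.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated dataset
(`Rscript analysis/01_simulate.R --seed 1`, then steps 02–07 in order).
Step 1 simulates 1000 circRNAs, 800 miRNAs and 2000 mRNAs with five sponge
triplets planted per comparison group; the later steps print:

```
circ: 1000/1000 expressed somewhere; 60.6% of those stage-specific
mirna: 800/800 expressed somewhere; 10.0% of those stage-specific
mrna: 2000/2000 expressed somewhere; 8.9% of those stage-specific
...
circ PreVsPro: 235 up, 225 down
...
PrePro_only: 5 triplets (5 circ, 5 miRNA, 5 mRNA, 10 edges); 5/5 planted recovered
ImmaturePre_only: 5 triplets (5 circ, 5 miRNA, 5 mRNA, 10 edges); 5/5 planted recovered
MatureImmature_only: 5 triplets (5 circ, 5 miRNA, 5 mRNA, 10 edges); 5/5 planted recovered
...
top term: network_associated (GeneRatio 15/15, p_adj 1.74e-25)
ddCt demonstration: Ct shift of -2 cycles -> fold change 4.0
```

The stage-specific percentages sit where the generator planted them (60% /
8% / 8%); every planted triplet is recovered with none spurious; the
network's target genes light up the seeded annotation term; and a −2-cycle
ΔΔCt converts to a 4-fold change. Tables, networks (SIF/GraphML) and the
ground truth live under `results/`.

Programmatic use mirrors the scripts:

```r
library(bcellcerna)
res <- generate_dataset(simulation_config(rng_seed = 1))
expressed <- call_expressed(res$dataset$circ)
calls <- classify_specificity(expressed)
de <- call_de_all(res$dataset$circ_counts, res$dataset$lib_sizes)
```

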