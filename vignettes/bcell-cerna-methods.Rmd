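---
title: "Methods: stage-specific expression and ceRNA network inference across B-cell development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specific expression and ceRNA network inference across B-cell development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`bcellcerna`: what each stage of the pipeline computes, which knobs matter,
what the synthetic generator does and does not emulate, and where the
design was genuinely open.

## The setting

Four sorted B-cell populations from bone marrow — pro-B, pre-B, immature,
mature — each profiled once as a pooled library (cells from several mice
per pool, no biological replicates) across three omics layers: circRNAs
quantified in reads per million (RPM), miRNAs in transcripts per million
(TPM), and mRNAs in FPKM. The analysis asks which transcripts are
stage-specific, which change between adjacent stages, what temporal shape
those changes take, and which circRNAs could act as miRNA sponges
(ceRNAs) that derepress specific mRNAs.

## Expressed calls and stage-specificity

No published threshold defines "expressed" for this design, so the rule is
explicit: with the default `threshold = 0` a transcript is expressed in a
stage when its normalized value is strictly positive; with a positive
threshold the rule is `value >= threshold` (boundary inclusive). Every
transcript then receives its exact expressed-stage subset — one of the 15
non-empty Venn classes or `not_expressed` — and *stage-specific* means a
singleton class. `specificity_fraction()` reports, per stage, specific /
expressed-in-stage, and returns `NA` (never 0) when nothing is expressed
in a stage. Inter-stage similarity is Pearson correlation of the raw
normalized columns (a `log1p` option exists but is off by default, since
the quantity of interest is total expression level); zero-variance stages
give `NA` entries with a warning, never a silent 0.

## Differential expression without replicates

With one pooled library per stage, variance cannot be estimated from
replicates, so DE testing uses the exact conditional count test for two
libraries: conditional on count $x$ in a library of size $N_1$, the count
$y$ in a library of size $N_2$ follows

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

which is negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The two-sided p-value doubles the smaller of
$F(y)=P(Y \le y)$ and $1-F(y)$, capped at 1. This convention was chosen
deliberately: doubling the smaller of the two *inclusive* tails is not
invariant under exchanging the roles of the two libraries for small
counts, whereas the $F$ / $1-F$ form is exactly swap-symmetric (the two
lower-tail binomial representations are complementary) and yields $p = 1$
for equal counts at equal depths. Both tails are computed directly (no
$1-F$ subtraction), so tiny p-values keep full relative precision.

The DE decision follows the printed rule of the study design this mirrors:
raw $p < 0.05$ (strict) **and** $|\log_2 \mathrm{FC}| \ge 1$ (inclusive).
A BH-adjusted p is reported alongside but not used for the flag. The
displayed log2 fold change is computed on counts-per-million with a
pseudocount (default 1.0 in normalized units), so zero counts are defined
and $\log_2\mathrm{FC}(0,0) = 0$; significance always comes from the raw
counts. Under a null simulation (equal Poisson rates, mean 100, 2000
transcripts) the test's empirical false-positive rate at $p<0.05$ is about
0.045; planted four-fold effects at mean count 100 are recovered with
sensitivity ≈ 1.

## Temporal patterns

Rather than model-profile clustering with permutation significance, each
trajectory is binned deterministically: normalize to the pro-B stage
(pseudocount, so the first element is exactly 1), then label each of the
three transitions `up` when the consecutive ratio exceeds $1+\delta$,
`down` below $1/(1+\delta)$, and `flat` otherwise. The default
$\delta = 0.2$ (a 20 % relative dead band) separates noise-level wobble
from the two-fold-and-larger steps the analysis cares about. The 27
possible sign words partition all trajectories; the labels are invariant
to overall scale, and reversing the stage order flips the word symbol-wise
— both properties are tested. The ratio (not difference) thresholding
matches the fold-change semantics used everywhere else.

## Seed matching

The bundled target predictor implements canonical seed sites only, on the
target read 5'→3' in transcript sense (the target is never
reverse-complemented; only the miRNA seed is):

| type | target string | length |
|---|---|---|
| 8mer | revcomp(miRNA[2..8]) + `A` | 8 |
| 7mer-m8 | revcomp(miRNA[2..8]) | 7 |
| 7mer-A1 | revcomp(miRNA[2..7]) + `A` | 7 |
| 6mer | revcomp(miRNA[2..7]) | 6 |

Coordinates are 0-based half-open. When several types share a start
position only the best (8mer > 7mer-m8 > 7mer-A1 > 6mer) is reported, to
avoid double-counting nested sites; sites at different starts are all
reported. There is no G:U wobble, 3'-supplementary pairing, free-energy or
conservation scoring — the matcher is a deterministic, exhaustively
testable stand-in, and tables exported from external databases can be
merged in with provenance retained (`merge_interactions()` takes the
union; how multiple external tools' predictions ought to be combined is
not standardized, so union with recorded sources is the least-committal
choice). circRNAs are scanned along their full provided sequence; for
mRNAs the supplied sequence should be the 3'UTR (documented, not
enforced).

## ceRNA assembly

Transcripts DE in exactly one of the three comparisons form exclusive
groups ("X (+) other (-)"); DE in zero or several comparisons means
`none`. Exclusivity is evaluated per transcript within each layer — the
grouping figure this mirrors is drawn per layer, and the joint-across-layer
reading would only shrink the networks; it is not implemented. A triplet
(circRNA, miRNA, mRNA) is emitted for a group when all three members are
in it, the miRNA has an interaction with both partners (the shared-MRE
requirement read as: same miRNA, a response element on each partner), and
directions satisfy sign(circ) = sign(mRNA) = −sign(miRNA) — decreased
circRNAs / increased miRNAs / decreased mRNAs, or the mirror scheme. No
minimum-site-count or expression-correlation filter is applied by default
(none is part of the design being mirrored); a site-count knob exists.
Output is complete and sorted; `network_summary()` counts distinct members
and de-duplicated edges.

## Enrichment and qPCR arithmetic

Over-representation uses the upper-tail ("at least k") hypergeometric
probability with $k$ = query genes in the term, $n$ = annotated query
genes, $K$ = background genes in the term, $N$ = annotated background.
Unless a universe is supplied, the background is every gene with at least
one annotation in the GMT — the convention of the common enrichment
tooling this replaces, since no universe was specified. Correction is
Benjamini–Hochberg (the usual default behind "corrected p values");
`significant` means adjusted p < 0.05. Terms with no background member
are skipped; query genes outside the background are dropped with a
warning. `GeneRatio` is the exact string `k/n`. The qPCR side is the
comparative-Ct method: $\Delta Ct$ against a housekeeping reference
(Gapdh or U6) in each sample, $\Delta\Delta Ct$ condition minus control,
fold change $2^{-\Delta\Delta Ct}$.

## The synthetic generator

`generate_dataset()` plants, in this order: per-layer stage-specific
transcripts (each specific with probability `frac_stage_specific`,
defaults 0.60 / 0.08 / 0.08 for circ / miRNA / mRNA — the regime where
circRNAs are strongly stage-restricted and the other layers are not);
sponge triplets (default 5 per exclusive group, members four-fold DE in
exactly their group's comparison with sponge-consistent directions);
circRNA temporal patterns (two-fold steps per transition); and extra DE
transcripts. Planted roles are drawn from the non-stage-specific pool; if
the pool is too small the generator stops with the violated bound named.
Expressed baselines are `baseline_mean` (default 100 counts) with
log-normal heterogeneity (sd 0.5 on the log scale); non-expressed stages
have mean zero. Counts are Poisson by default — with pooled libraries and
no replicate structure there is nothing to estimate a dispersion from, so
the minimal count-noise model is the default and negative binomial (user
dispersion, `size = 1/dispersion`) is the option. `replicates_per_stage`
(default 1, the pooled design) sums that many independent draws per stage
and scales the library sizes to match.

Units: RPM/TPM are count / library_size × 10⁶ (the simulated miRNA counts
are already transcript-level, so TPM reduces to counts-per-million); FPKM
is count / (library_size/10⁶ × length/10³) with effective lengths drawn
uniformly in [500, 5000] nt — the FPKM computation upstream of data like
these is never specified, so the convention is stated here and applied
consistently. `sequencing_depth` is the normalization denominator, as in
"per million mapped reads"; it is not the column sum of the simulated
transcript set.

**Hard planting** writes the expected values through deterministically
(counts = rounded means, normalized values from the exact means), so
exact-recovery tests are free of sampling noise. **Sequences**: planted
targets carry one exact 8mer per planted miRNA at a recorded position;
background is uniform ACGU, rejection-sampled so that non-planted pairs
contain no 6mer-or-better site anywhere (every canonical site type
contains the 6mer core as a substring, so one check suffices). miRNA seed
regions are resampled until mutually non-colliding, and a cap of 1000
attempts per sequence turns pathological configurations into a hard error
rather than a hang. By default sequences are generated for planted triplet
members only (`sequence_scope = "planted"`); `"all"` is available, but
with many miRNAs the no-spurious-site constraint becomes increasingly
expensive and can exhaust the cap — by design.

What the generator does **not** emulate: read-level noise, isoform
structure, back-splice junctions, mapping ambiguity, cross-layer
correlation beyond the planted triplets, or realistic sequence
composition. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct under its own assumptions, not that those
assumptions hold for any particular real dataset.

## Numerical choices and degenerate inputs

- Expressed-call boundary: `>= threshold` for positive thresholds, `> 0`
  at the default 0.
- `log2_fold_change(0, 0, pc)` is 0 by the pseudocount rule; pseudocounts
  must be strictly positive.
- The count test caps at 1, is strictly positive, and is monotone: at
  fixed totals, more divergent counts never get a larger p (tested).
- `specificity_fraction` with an empty denominator returns `NA`;
  zero-variance correlations are `NA` with a warning.
- Venn tallies always cover all 16 classes so they sum to the transcript
  count; empty matrices give empty summaries, not errors.
- All writers are deterministic (sorted nodes/edges, fixed number
  formatting); `read(write(x)) == x` for matrices, interaction tables,
  networks, ground truth and configs, and doubles survive the TSV round
  trip exactly.
- Positions in all outputs are 0-based half-open; sequences are RNA
  internally (T→U on input, U on output).

## Problem sizes

The test-suite and acceptance-script simulations use 100–1000 transcripts
per layer, 2000-transcript null/effect simulations for test calibration,
500 random miRNA–target pairs (targets ≤ 200 nt) for matcher–oracle
equivalence, 50 random instances (≤ 20 ids per layer) for exhaustive
triplet enumeration, and universes ≤ 30 genes for exhaustive
hypergeometric enumeration — sizes at which the brute-force oracles are
exact and the whole suite runs in well under a minute per component.

## Known limitations

- The conditional count test treats the pooled library as the unit of
  inference; biological replicate variance is out of reach by design, and
  dispersion-aware methods should replace it the moment replicates exist.
- The seed matcher's canonical-site model has no affinity or context
  scoring; its predictions are best treated as a transparent baseline or
  as scaffolding for externally loaded interaction tables.
- Sign-word pattern labels depend on the dead band δ near ratio
  boundaries; they are bins, not tests, and carry no significance measure.
- Enrichment results are only as meaningful as the supplied annotation and
  universe; with the default annotated-background convention, changing the
  GMT changes N.
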