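#' Log2 fold change with pseudocount
#'
#' `log2((numerator + pc) / (denominator + pc))`. The pseudocount keeps the
#' ratio defined when either side is zero; with both sides zero the fold
#' change is 0 by construction.
#'
#' @param numerator,denominator Nonnegative values (vectorized).
#' @param pseudocount Positive pseudocount in the same (normalized) unit.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(numerator, denominator, pseudocount = 1) {
  .stop_if(!is.numeric(pseudocount) || length(pseudocount) != 1L ||
             is.na(pseudocount) || pseudocount <= 0,
           "`pseudocount` must be a single positive number")
  .stop_if(any(numerator < 0) || any(denominator < 0),
           "expression values must be nonnegative")
  log2((numerator + pseudocount) / (denominator + pseudocount))
}

#' Conditional count test for two pooled libraries (no replicates)
#'
#' Exact test for a difference in relative abundance of one transcript
#' between two sequencing libraries without replicates (Audic-Claverie
#' style). Conditional on the first library's count `x`, the second count
#' follows
#' \deqn{P(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^{x+y+1}),}
#' i.e. a negative binomial with size `x + 1` and success probability
#' `N1 / (N1 + N2)`. The two-sided p-value doubles the smaller of the
#' lower-tail probability `F(y) = P(Y <= y)` and its complement
#' `1 - F(y)`, capped at 1. This convention is exactly symmetric under
#' swapping `(x, N1)` with `(y, N2)` and yields p = 1 when `x == y` with
#' equal library sizes.
#'
#' @param x,y Nonnegative integer counts (vectorized).
#' @param n1,n2 Positive library sizes for the two stages.
#' @return p-values in (0, 1].
#' @export
count_test <- function(x, y, n1, n2) {
  .stop_if(any(n1 <= 0) || any(n2 <= 0), "library sizes must be positive")
  .stop_if(any(x < 0) || any(y < 0), "counts must be nonnegative")
  .stop_if(any(x != floor(x)) || any(y != floor(y)),
           "counts must be integers")
  q <- n1 / (n1 + n2)
  lo <- stats::pnbinom(y, size = x + 1, prob = q)               # P(Y <= y)
  hi <- stats::pnbinom(y, size = x + 1, prob = q,
                       lower.tail = FALSE)                      # P(Y > y)
  pmin(1, 2 * pmin(lo, hi))
}

#' Call differential expression between two adjacent stages
#'
#' Applies the published decision rule — raw p-value < `alpha` and
#' |log2FC| >= `lfc_min` — per transcript between the two stages of one
#' adjacent-stage comparison. Significance comes from [count_test()] on raw
#' counts; the displayed log2 fold change is computed on counts-per-million
#' values with a pseudocount. A BH-adjusted p-value is reported alongside
#' but deliberately not used for the DE flag, matching the raw-p rule.
#'
#' @param counts_num,counts_den Named nonnegative integer count vectors for
#'   the numerator (later) and denominator (earlier) stage; names are
#'   transcript ids and must match as sets.
#' @param lib_num,lib_den Positive library sizes of the two stages.
#' @param comparison Comparison label (one of
#'   `adjacent_comparisons()$label`, or any string for ad-hoc use).
#' @param alpha Raw p-value cutoff (strict `<`).
#' @param lfc_min Minimum absolute log2 fold change (inclusive `>=`).
#' @param pseudocount Pseudocount for the displayed log2FC, in
#'   counts-per-million units.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `comparison`, `log2fc`, `p`, `p_adj`, `direction` (up/down/none),
#'   `is_de`.
#' @export
call_de <- function(counts_num, counts_den, lib_num, lib_den,
                    comparison = "PreVsPro",
                    alpha = 0.05, lfc_min = 1, pseudocount = 1) {
  .stop_if(is.null(names(counts_num)) || is.null(names(counts_den)),
           "count vectors must be named by transcript id")
  only_num <- setdiff(names(counts_num), names(counts_den))
  only_den <- setdiff(names(counts_den), names(counts_num))
  .stop_if(length(only_num) + length(only_den) > 0,
           "mismatched transcript ids; only in numerator: [",
           paste(only_num, collapse = ", "), "]; only in denominator: [",
           paste(only_den, collapse = ", "), "]")
  ids <- names(counts_num)
  den <- counts_den[ids]

  cpm_num <- counts_num / lib_num * 1e6
  cpm_den <- den / lib_den * 1e6
  lfc <- log2_fold_change(cpm_num, cpm_den, pseudocount)
  # count_test is symmetric, so orientation does not affect p
  p <- count_test(den, counts_num, lib_den, lib_num)
  p_adj <- stats::p.adjust(p, method = "BH")
  is_de <- (p < alpha) & (abs(lfc) >= lfc_min)
  direction <- ifelse(!is_de, "none", ifelse(lfc > 0, "up", "down"))
  data.frame(
    transcript_id = ids,
    comparison    = comparison,
    log2fc        = unname(lfc),
    p             = unname(p),
    p_adj         = unname(p_adj),
    direction     = unname(direction),
    is_de         = unname(is_de),
    stringsAsFactors = FALSE
  )
}

#' DE calls for all three adjacent-stage comparisons
#'
#' Convenience wrapper running [call_de()] for PreVsPro, ImmatureVsPre and
#' MatureVsImmature on a four-stage count matrix.
#'
#' @param counts Count matrix (transcripts x 4 ordered stages).
#' @param lib_sizes Positive library sizes, length 4 (stage order) or named
#'   by stage.
#' @param ... Passed to [call_de()].
#' @return Row-bound data.frame of DE records for the three comparisons.
#' @export
call_de_all <- function(counts, lib_sizes, ...) {
  .check_four_stages(counts)
  stages <- b_cell_stages()
  if (!is.null(names(lib_sizes))) lib_sizes <- lib_sizes[stages]
  .stop_if(length(lib_sizes) != 4L || anyNA(lib_sizes),
           "`lib_sizes` must give one positive size per stage")
  cmp <- adjacent_comparisons()
  out <- lapply(seq_len(nrow(cmp)), function(i) {
    num <- cmp$numerator[i]; den <- cmp$denominator[i]
    call_de(counts[, num], counts[, den],
            lib_sizes[match(num, stages)], lib_sizes[match(den, stages)],
            comparison = cmp$label[i], ...)
  })
  do.call(rbind, out)
}

#' Up/down DE counts per comparison
#'
#' The summary statistic of the adjacent-stage DE analysis: how many
#' transcripts are up- and downregulated in each comparison.
#'
#' @param de data.frame of DE records (e.g. from [call_de_all()]).
#' @return data.frame with columns `comparison`, `n_up`, `n_down`.
#' @export
de_summary <- function(de) {
  comps <- unique(de$comparison)
  data.frame(
    comparison = comps,
    n_up   = vapply(comps, function(cc)
      sum(de$comparison == cc & de$direction == "up"), integer(1L)),
    n_down = vapply(comps, function(cc)
      sum(de$comparison == cc & de$direction == "down"), integer(1L)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
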