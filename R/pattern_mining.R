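#' Normalize a four-stage profile to the pro-B (first) stage
#'
#' Divides every value (plus pseudocount) by the first-stage value (plus
#' pseudocount), so the first element is exactly 1 and later elements are
#' fold changes relative to pro-B.
#'
#' @param profile Numeric vector of 4 nonnegative values in stage order.
#' @param pseudocount Positive pseudocount.
#' @return Numeric vector of 4 positive values, first element 1.
#' @export
normalize_to_reference <- function(profile, pseudocount = 1) {
  .stop_if(!is.numeric(pseudocount) || length(pseudocount) != 1L ||
             pseudocount <= 0, "`pseudocount` must be a single positive number")
  .stop_if(any(profile < 0), "profile values must be nonnegative")
  (profile + pseudocount) / (profile[1L] + pseudocount)
}

# the three stage transitions, in order
.transitions <- c("pro>pre", "pre>immature", "immature>mature")

#' All 27 temporal pattern labels
#'
#' Every word of three symbols from \{up, down, flat\}, one symbol per stage
#' transition (pro->pre, pre->immature, immature->mature), joined by `-`.
#' "up-up-up" is the continuously-increased pattern and "down-down-down"
#' the continuously-decreased one.
#'
#' @return Character vector of the 27 labels.
#' @export
pattern_labels_all <- function() {
  sym <- c("up", "down", "flat")
  g <- expand.grid(s3 = sym, s2 = sym, s1 = sym,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(paste(g$s1, g$s2, g$s3, sep = "-"))
}

#' Classify a four-stage trajectory into a sign-word pattern
#'
#' Each stage transition is labelled `up` when the ratio of consecutive
#' values exceeds `1 + delta`, `down` when it is below `1 / (1 + delta)`,
#' and `flat` otherwise (a relative dead band). The label is the three
#' symbols joined by `-`, e.g. `"down-up-down"`.
#'
#' @param profile Numeric vector of 4 positive values (normalized profile).
#' @param delta Nonnegative relative threshold for calling a transition
#'   up or down (default 0.2, i.e. a 20 percent change).
#' @return A single pattern label string.
#' @export
classify_pattern <- function(profile, delta = 0.2) {
  .stop_if(length(profile) != 4L, "profile must have 4 stages")
  .stop_if(any(!is.finite(profile)) || any(profile <= 0),
           "normalized profile values must be positive")
  .stop_if(delta < 0, "`delta` must be nonnegative")
  r <- profile[-1L] / profile[-4L]
  sym <- ifelse(r > 1 + delta, "up",
                ifelse(r < 1 / (1 + delta), "down", "flat"))
  paste(sym, collapse = "-")
}

#' Tally temporal patterns over a four-stage matrix
#'
#' Normalizes every transcript's profile to the pro-B stage, classifies it
#' with [classify_pattern()], and counts transcripts per pattern label.
#' Every transcript receives exactly one of the 27 labels, so the counts
#' sum to the number of transcripts.
#'
#' @param matrix Numeric matrix (transcripts x 4 ordered stages).
#' @param delta Relative threshold, see [classify_pattern()].
#' @param pseudocount Pseudocount for the reference normalization.
#' @return Named integer vector of counts over the observed labels
#'   (empty for an empty matrix). The per-transcript labels are attached
#'   as attribute `"labels"` (named character vector).
#' @export
summarize_patterns <- function(matrix, delta = 0.2, pseudocount = 1) {
  m <- .as_plain_matrix(matrix)
  .check_four_stages(m)
  if (nrow(m) == 0L) {
    out <- integer(0)
    attr(out, "labels") <- stats::setNames(character(0), character(0))
    return(out)
  }
  labels <- apply(m, 1L, function(v)
    classify_pattern(normalize_to_reference(v, pseudocount), delta))
  tab <- table(labels)
  out <- as.integer(tab)
  names(out) <- names(tab)
  attr(out, "labels") <- labels
  out
}
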