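#' Call transcripts expressed per stage
#'
#' Marks a transcript as expressed in a stage when its normalized value
#' reaches the threshold. With the default `threshold = 0` any strictly
#' positive value counts as expressed; with a positive threshold the rule
#' is `value >= threshold` (boundary inclusive). No published definition of
#' "expressed" exists for this design, so the threshold is explicit.
#'
#' @param matrix Numeric matrix (transcripts x stages) of nonnegative values,
#'   typically an [expression_matrix()].
#' @param threshold Nonnegative expressed-call threshold in the matrix's
#'   normalized unit.
#' @return Logical matrix with the same dimnames.
#' @export
call_expressed <- function(matrix, threshold = 0) {
  .stop_if(!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold),
           "`threshold` must be a single number")
  .stop_if(threshold < 0, "`threshold` must be nonnegative")
  m <- .as_plain_matrix(matrix)
  .stop_if(anyNA(m), "matrix must not contain missing values")
  .stop_if(any(m < 0), "matrix values must be nonnegative")
  if (threshold > 0) m >= threshold else m > 0
}

.subset_label <- function(stages) {
  if (length(stages) == 0L) "not_expressed" else paste(stages, collapse = "+")
}

#' Classify stage-specificity (Venn classes)
#'
#' Assigns every transcript its exact expressed-stage subset: one of the 15
#' non-empty subsets of the four stages, or `"not_expressed"`. A transcript
#' is stage-specific when it is expressed in exactly one stage (the Venn
#' singleton classes).
#'
#' @param expressed Logical matrix (transcripts x 4 stages) from
#'   [call_expressed()].
#' @return data.frame with columns `transcript_id`, `expressed_stages`
#'   (stage names joined by `+`, or `"not_expressed"`), `class` (same
#'   labelling), `n_stages`, and `is_stage_specific`.
#' @export
classify_specificity <- function(expressed) {
  .stop_if(!is.logical(expressed) || !is.matrix(expressed),
           "`expressed` must be a logical matrix")
  .check_four_stages(expressed)
  stages <- colnames(expressed)
  labs <- apply(expressed, 1L, function(fl) .subset_label(stages[fl]))
  n <- rowSums(expressed)
  data.frame(
    transcript_id     = rownames(expressed),
    expressed_stages  = unname(labs),
    class             = unname(labs),
    n_stages          = unname(n),
    is_stage_specific = unname(n == 1L),
    stringsAsFactors  = FALSE
  )
}

#' Counts per Venn class
#'
#' Tallies transcripts over all 16 expressed-stage subsets (15 non-empty
#' classes plus `"not_expressed"`), including empty classes, so the counts
#' always sum to the number of transcripts.
#'
#' @param expressed Logical matrix (transcripts x 4 stages).
#' @return Named integer vector over the 16 classes.
#' @export
venn_counts <- function(expressed) {
  calls <- classify_specificity(expressed)
  stages <- colnames(expressed)
  all_classes <- c(
    unlist(lapply(seq_along(stages), function(k) {
      utils::combn(stages, k, FUN = .subset_label)
    })),
    "not_expressed"
  )
  counts <- table(factor(calls$class, levels = all_classes))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Fraction of stage-expressed transcripts that are specific to that stage
#'
#' For one stage, the number of transcripts specific to it divided by the
#' number of transcripts expressed in it. Returns `NA` (not 0) when no
#' transcript is expressed in the stage.
#'
#' @param calls data.frame from [classify_specificity()].
#' @param stage One of the four stage labels.
#' @return A fraction in \code{[0, 1]}, or `NA_real_` when undefined.
#' @export
specificity_fraction <- function(calls, stage) {
  .stop_if(!stage %in% b_cell_stages(),
           "unknown stage label: ", stage)
  in_stage <- vapply(
    strsplit(calls$expressed_stages, "+", fixed = TRUE),
    function(s) stage %in% s, logical(1L)
  )
  denom <- sum(in_stage)
  if (denom == 0L) return(NA_real_)
  sum(in_stage & calls$is_stage_specific) / denom
}

#' Pairwise Pearson correlation between stages
#'
#' Pearson correlation of total transcript expression levels between every
#' pair of stages, computed on the raw normalized values by default (a
#' `log1p` transform is available but off by default). Entries involving a
#' zero-variance stage are undefined and returned as `NA` with a warning,
#' never silently as 0; the diagonal is 1.
#'
#' @param matrix Numeric matrix (transcripts x stages), >= 2 transcripts.
#' @param log1p Apply `log1p` before correlating.
#' @return Symmetric numeric matrix (stages x stages) with unit diagonal.
#' @export
stage_correlation <- function(matrix, log1p = FALSE) {
  m <- .as_plain_matrix(matrix)
  .stop_if(nrow(m) < 2L, "need at least 2 transcripts to correlate stages")
  if (log1p) m <- log1p(m)
  sds <- apply(m, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(r) <- 1
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    warning("zero-variance stage(s), correlation undefined: ",
            paste(bad, collapse = ", "), call. = FALSE)
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
    diag(r) <- 1
  }
  r
}
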