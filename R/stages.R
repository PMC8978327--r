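#' Ordered B-cell developmental stages
#'
#' The four bone-marrow B-cell developmental stages used throughout the
#' pipeline, in developmental order: pro-B, pre-B, immature, mature.
#'
#' @return Character vector of length 4.
#' @export
b_cell_stages <- function() {
  c("pro-B", "pre-B", "immature", "mature")
}

#' Adjacent-stage comparisons
#'
#' The three pairwise comparisons between consecutive developmental stages.
#' The numerator is always the later (more mature) stage, so a positive
#' log2 fold change means expression increases along development.
#'
#' @return A data.frame with columns `label`, `numerator`, `denominator`.
#' @export
adjacent_comparisons <- function() {
  data.frame(
    label       = c("PreVsPro", "ImmatureVsPre", "MatureVsImmature"),
    numerator   = c("pre-B", "immature", "mature"),
    denominator = c("pro-B", "pre-B", "immature"),
    stringsAsFactors = FALSE
  )
}

# comparison label -> exclusive group label
.exclusive_group_of <- c(
  PreVsPro         = "PrePro_only",
  ImmatureVsPre    = "ImmaturePre_only",
  MatureVsImmature = "MatureImmature_only"
)

#' Exclusive comparison-group labels
#'
#' Group labels for transcripts differentially expressed in exactly one
#' adjacent-stage comparison ("X (+) other (-)" in the grouping scheme),
#' plus `"none"` for transcripts DE in zero or in two or more comparisons.
#'
#' @return Character vector of the three group labels and `"none"`.
#' @export
exclusive_groups <- function() {
  c(unname(.exclusive_group_of), "none")
}

.stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Construct an expression matrix
#'
#' A light container for a transcripts-by-stages matrix of nonnegative
#' normalized expression values carrying its unit tag (RPM for circRNAs,
#' TPM for miRNAs, FPKM for mRNAs).
#'
#' @param values Numeric matrix; rownames are transcript ids, colnames are
#'   stage labels.
#' @param unit One of "RPM", "TPM", "FPKM".
#' @return The matrix with a `unit` attribute and class `expr_matrix`.
#' @export
expression_matrix <- function(values, unit = c("RPM", "TPM", "FPKM")) {
  unit <- match.arg(unit)
  .stop_if(!is.matrix(values) || !is.numeric(values),
           "`values` must be a numeric matrix")
  .stop_if(is.null(rownames(values)) && nrow(values) > 0,
           "`values` must have transcript ids as rownames")
  .stop_if(is.null(colnames(values)), "`values` must have stage labels as colnames")
  .stop_if(anyNA(values), "expression values must not contain missing values")
  .stop_if(any(values < 0), "expression values must be nonnegative")
  .stop_if(anyDuplicated(rownames(values)) > 0, "duplicate transcript ids")
  attr(values, "unit") <- unit
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Unit tag of an expression matrix
#' @param x An `expr_matrix`.
#' @return The unit string ("RPM", "TPM" or "FPKM"), or `NULL`.
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d transcripts x %d stages [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  y <- x
  attr(y, "unit") <- NULL
  class(y) <- "matrix"
  print(utils::head(y, 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# strip class/attr, return plain numeric matrix
.as_plain_matrix <- function(x) {
  attr(x, "unit") <- NULL
  cls <- class(x)
  class(x) <- cls[cls != "expr_matrix"]
  x
}

.check_four_stages <- function(x) {
  .stop_if(!identical(colnames(x), b_cell_stages()),
           "matrix must have the four ordered stage columns: ",
           paste(b_cell_stages(), collapse = ", "))
}
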