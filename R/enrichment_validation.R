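#' Hypergeometric over-representation test for gene sets
#'
#' For each annotation term, tests whether the query gene list contains at
#' least as many term members as expected by chance when drawing from the
#' annotated background (upper-tail hypergeometric probability,
#' "at least k"). P-values are Benjamini-Hochberg adjusted across all
#' tested terms; terms with no background member are skipped. Unless a
#' background universe is supplied, it defaults to every gene with at
#' least one annotation in `annotations`.
#'
#' @param query Character vector of query gene ids. Genes outside the
#'   background are dropped with a warning.
#' @param annotations Named list: term id -> character vector of member
#'   genes (e.g. from [read_gmt()]).
#' @param background Optional character vector of universe gene ids.
#' @param term_names Optional named character vector of term descriptions.
#' @param alpha Adjusted-p cutoff for the `significant` flag.
#' @return data.frame sorted by p (ties broken by term id) with columns
#'   `term_id`, `term_name`, `k` (query genes in term), `n` (annotated
#'   query genes), `K` (background genes in term), `N` (annotated
#'   background size), `gene_ratio` ("k/n"), `p`, `p_adj`, `significant`,
#'   `genes` (slash-joined query hits).
#' @export
hypergeometric_enrich <- function(query, annotations, background = NULL,
                                  term_names = NULL, alpha = 0.05) {
  .stop_if(length(annotations) > 0 && is.null(names(annotations)),
           "`annotations` must be a named list")
  annotations <- lapply(annotations, unique)
  annotated <- unique(unlist(annotations, use.names = FALSE))
  if (is.null(background)) {
    background <- annotated
  } else {
    background <- unique(background)
  }
  .stop_if(length(background) == 0L, "empty background universe")

  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    query <- intersect(query, background)
  }

  bg_annotated <- intersect(background, annotated)
  n_query <- length(intersect(query, bg_annotated))
  big_n <- length(bg_annotated)

  empty <- data.frame(
    term_id = character(0), term_name = character(0),
    k = integer(0), n = integer(0), K = integer(0), N = integer(0),
    gene_ratio = character(0), p = numeric(0), p_adj = numeric(0),
    significant = logical(0), genes = character(0), stringsAsFactors = FALSE)
  if (n_query == 0L || length(annotations) == 0L) return(empty)

  rows <- lapply(names(annotations), function(term) {
    members <- intersect(annotations[[term]], background)
    big_k <- length(members)
    if (big_k == 0L) return(NULL)  # term absent from the background
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1L, big_k, big_n - big_k, n_query,
                       lower.tail = FALSE)
    data.frame(
      term_id = term,
      term_name = if (!is.null(term_names) && term %in% names(term_names))
        unname(term_names[[term]]) else term,
      k = k, n = n_query, K = big_k, N = big_n,
      gene_ratio = format_gene_ratio(k, n_query),
      p = p,
      genes = paste(sort(hits), collapse = "/"),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "k", "n", "K", "N", "gene_ratio",
               "p", "p_adj", "significant", "genes")]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-adjusted p-values: `p_adj(i) = min_{j >= rank(i)} (m/j) p_(j)`,
#' capped at 1; order-preserving.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  .stop_if(anyNA(p) || any(p < 0) || any(p > 1),
           "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Format an enrichment gene ratio
#'
#' The "k/n" notation used in enrichment tables: query genes in the term
#' over annotated query genes.
#'
#' @param k Hits in the term, `0 <= k <= n`.
#' @param n Annotated query size, `n > 0`.
#' @return The exact string `"k/n"`, no padding.
#' @export
format_gene_ratio <- function(k, n) {
  .stop_if(any(n == 0), "gene-ratio denominator must be positive")
  .stop_if(any(k < 0) || any(k > n), "need 0 <= k <= n")
  sprintf("%d/%d", as.integer(k), as.integer(n))
}

#' Parse a gene-ratio string back to (k, n)
#' @param x Strings of the form "k/n".
#' @return data.frame with integer columns `k` and `n`.
#' @export
parse_gene_ratio <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  .stop_if(any(lengths(parts) != 2L), "malformed gene ratio")
  data.frame(
    k = vapply(parts, function(p) as.integer(p[1L]), integer(1L)),
    n = vapply(parts, function(p) as.integer(p[2L]), integer(1L))
  )
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' The comparative cycle-threshold method: the target gene's Ct is first
#' referenced to a housekeeping gene (Gapdh or U6) within each sample
#' (dCt = Ct_target - Ct_reference), then the condition is referenced to
#' the control (ddCt = dCt_condition - dCt_control), and the fold change
#' is `2^-ddCt`.
#'
#' @param ct_target_cond,ct_ref_cond Ct values (cycles) of the target and
#'   reference gene in the condition sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return Fold change (positive real), vectorized.
#' @export
delta_delta_ct <- function(ct_target_cond, ct_ref_cond,
                           ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_cond, ct_ref_cond, ct_target_ctrl, ct_ref_ctrl)
  .stop_if(anyNA(cts) || any(cts <= 0), "Ct values must be positive")
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
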