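#' Assign transcripts to exclusive comparison groups
#'
#' A transcript belongs to group "X_only" when it is differentially
#' expressed in comparison X and in no other adjacent-stage comparison
#' (the "X (+) other (-)" grouping). Transcripts DE in zero or in two or
#' more comparisons are labelled `"none"`.
#'
#' @param de data.frame of DE records covering all three comparisons for
#'   every transcript (columns `transcript_id`, `comparison`, `direction`,
#'   `is_de`), e.g. from [call_de_all()].
#' @return data.frame with columns `transcript_id`, `group` (one of
#'   [exclusive_groups()]), `direction` (the direction within the
#'   transcript's exclusive comparison; `NA` for group `"none"`).
#' @export
assign_exclusive_groups <- function(de) {
  comps <- adjacent_comparisons()$label
  ids <- unique(de$transcript_id)
  have <- table(de$transcript_id, factor(de$comparison, levels = comps))
  missing <- rownames(have)[rowSums(have == 1L) != length(comps)]
  .stop_if(length(missing) > 0,
           "transcript(s) missing a comparison: ",
           paste(utils::head(missing, 10L), collapse = ", "))

  de_wide_is <- matrix(FALSE, length(ids), length(comps),
                       dimnames = list(ids, comps))
  de_wide_dir <- matrix(NA_character_, length(ids), length(comps),
                        dimnames = list(ids, comps))
  de_wide_is[cbind(de$transcript_id, de$comparison)] <- de$is_de
  de_wide_dir[cbind(de$transcript_id, de$comparison)] <- de$direction

  n_de <- rowSums(de_wide_is)
  group <- rep("none", length(ids))
  direction <- rep(NA_character_, length(ids))
  one <- which(n_de == 1L)
  if (length(one) > 0) {
    which_cmp <- apply(de_wide_is[one, , drop = FALSE], 1L, which)
    group[one] <- unname(.exclusive_group_of[comps[which_cmp]])
    direction[one] <- de_wide_dir[cbind(one, which_cmp)]
  }
  data.frame(
    transcript_id = ids,
    group = group,
    direction = direction,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# scheme implied by the miRNA direction (ceRNA: sponge and target move
# together, opposite to the miRNA)
.scheme_of_mir <- c(
  up   = "circ_down_mir_up_mrna_down",
  down = "circ_up_mir_down_mrna_up"
)

#' Assemble direction-consistent ceRNA triplets
#'
#' Builds every circRNA-miRNA-mRNA triplet in one exclusive comparison
#' group such that (i) the miRNA has a predicted or loaded interaction with
#' both the circRNA and the mRNA (shared miRNA response elements), (ii) all
#' three members belong to the requested group, and (iii) the directions
#' follow the ceRNA scheme: circRNA and mRNA move together, the miRNA
#' opposite (decreased circRNA - increased miRNA - decreased mRNA, or the
#' mirror scheme). The output is complete (no qualifying triplet omitted)
#' and sorted lexicographically by (circ, miRNA, mRNA).
#'
#' @param circ_groups,mirna_groups,mrna_groups Per-layer group tables from
#'   [assign_exclusive_groups()].
#' @param interactions An [interaction_table()] holding miRNA->circRNA and
#'   miRNA->mRNA edges.
#' @param group The exclusive group to assemble (one of the first three
#'   values of [exclusive_groups()]).
#' @param min_sites Optional minimum site count per edge (default 1, i.e.
#'   no extra filter beyond edge existence).
#' @return data.frame with columns `circ_id`, `mirna_id`, `mrna_id`,
#'   `group`, `scheme`.
#' @export
build_triplets <- function(circ_groups, mirna_groups, mrna_groups,
                           interactions, group, min_sites = 1L) {
  .stop_if(!group %in% setdiff(exclusive_groups(), "none"),
           "unknown group label: ", group)
  empty <- data.frame(circ_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), group = character(0),
                      scheme = character(0), stringsAsFactors = FALSE)
  circ <- circ_groups[circ_groups$group == group, , drop = FALSE]
  mir  <- mirna_groups[mirna_groups$group == group, , drop = FALSE]
  mrna <- mrna_groups[mrna_groups$group == group, , drop = FALSE]
  if (nrow(circ) == 0L || nrow(mir) == 0L || nrow(mrna) == 0L) return(empty)

  it <- as.data.frame(interactions)
  it <- it[it$n_sites >= min_sites, , drop = FALSE]
  e_circ <- it[it$target_kind == "circRNA", , drop = FALSE]
  e_mrna <- it[it$target_kind == "mRNA", , drop = FALSE]

  circ_dir <- stats::setNames(circ$direction, circ$transcript_id)
  mrna_dir <- stats::setNames(mrna$direction, mrna$transcript_id)

  rows <- list()
  for (i in seq_len(nrow(mir))) {
    m <- mir$transcript_id[i]
    d_m <- mir$direction[i]
    if (!d_m %in% names(.scheme_of_mir)) next
    partner_dir <- if (d_m == "up") "down" else "up"
    circs <- e_circ$target_id[e_circ$mirna_id == m]
    circs <- circs[circs %in% names(circ_dir)[circ_dir == partner_dir]]
    genes <- e_mrna$target_id[e_mrna$mirna_id == m]
    genes <- genes[genes %in% names(mrna_dir)[mrna_dir == partner_dir]]
    if (length(circs) == 0L || length(genes) == 0L) next
    g <- expand.grid(circ_id = circs, mrna_id = genes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$mirna_id <- m
    g$scheme <- unname(.scheme_of_mir[[d_m]])
    rows[[length(rows) + 1L]] <- g
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$group <- group
  out <- out[order(out$circ_id, out$mirna_id, out$mrna_id),
             c("circ_id", "mirna_id", "mrna_id", "group", "scheme")]
  rownames(out) <- NULL
  out
}

#' Summary counts of a ceRNA network
#'
#' Distinct circRNAs, miRNAs and mRNAs in a triplet list, and the edge
#' count (distinct circRNA-miRNA pairs plus distinct miRNA-mRNA pairs;
#' triplets sharing an edge count it once).
#'
#' @param triplets data.frame from [build_triplets()].
#' @return Named list with `n_circ`, `n_mirna`, `n_mrna`, `n_edges`.
#' @export
network_summary <- function(triplets) {
  list(
    n_circ  = length(unique(triplets$circ_id)),
    n_mirna = length(unique(triplets$mirna_id)),
    n_mrna  = length(unique(triplets$mrna_id)),
    n_edges = nrow(unique(triplets[, c("circ_id", "mirna_id")])) +
              nrow(unique(triplets[, c("mirna_id", "mrna_id")]))
  )
}
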