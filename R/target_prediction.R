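# Canonical miRNA seed matching. Site hierarchy, best first:
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

.validate_rna <- function(seq, what) {
  .stop_if(!is.character(seq) || length(seq) != 1L || is.na(seq),
           "`", what, "` must be a single string")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "U"))
  .stop_if(length(bad) > 0,
           "non-ACGU character '", chars[bad[1L]], "' in ", what,
           " at position ", bad[1L])
  invisible(chars)
}

#' Reverse complement of an RNA string
#' @param seq RNA string over ACGU, 5'->3'.
#' @return The reverse complement, 5'->3'.
#' @export
revcomp_rna <- function(seq) {
  .validate_rna(seq, "seq")
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# the four canonical site strings implied by a miRNA sequence, target sense
.seed_site_strings <- function(mirna_seq) {
  seed7 <- revcomp_rna(substr(mirna_seq, 2L, 8L)) # matches miRNA nt 2-8
  seed6 <- revcomp_rna(substr(mirna_seq, 2L, 7L)) # matches miRNA nt 2-7
  c("8mer"    = paste0(seed7, "A"),
    "7mer-m8" = seed7,
    "7mer-A1" = paste0(seed6, "A"),
    "6mer"    = seed6)
}

# all (possibly overlapping) 1-based start positions of `pattern` in `text`
.match_starts <- function(pattern, text_rna) {
  if (nchar(pattern) > length(text_rna)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(pattern, text_rna))
}

#' Find canonical seed-match sites of a miRNA on a target sequence
#'
#' Scans the target (transcript-sense, 5'->3') for the four canonical site
#' types of the miRNA seed: 8mer (= reverse complement of miRNA nt 2-8
#' followed by A), 7mer-m8 (reverse complement of nt 2-8), 7mer-A1
#' (reverse complement of nt 2-7 followed by A) and 6mer (reverse
#' complement of nt 2-7). Only the miRNA seed is complemented; the target
#' is never reverse-complemented. When several site types share a start
#' position only the best (8mer > 7mer-m8 > 7mer-A1 > 6mer) is reported.
#'
#' @param mirna_seq miRNA sequence, RNA 5'->3', length >= 8.
#' @param target_seq Target sequence, RNA transcript sense.
#' @return data.frame with columns `site_type`, `start`, `end` (0-based,
#'   half-open coordinates on the target), sorted by `start`.
#' @export
find_seed_matches <- function(mirna_seq, target_seq) {
  .validate_rna(mirna_seq, "mirna_seq")
  .validate_rna(target_seq, "target_seq")
  .stop_if(nchar(mirna_seq) < 8L, "miRNA must be at least 8 nt")
  sites <- .seed_site_strings(mirna_seq)
  target <- Biostrings::RNAString(target_seq)
  best <- list()  # start (1-based, as char key) -> type index
  for (k in seq_along(SITE_TYPES)) {
    type <- SITE_TYPES[k]
    for (s in .match_starts(sites[[type]], target)) {
      key <- as.character(s)
      if (is.null(best[[key]])) best[[key]] <- k
    }
  }
  if (length(best) == 0L) {
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  starts1 <- as.integer(names(best))
  types <- SITE_TYPES[unlist(best)]
  widths <- nchar(sites[types])
  ord <- order(starts1)
  data.frame(
    site_type = types[ord],
    start     = starts1[ord] - 1L,
    end       = starts1[ord] - 1L + unname(widths[ord]),
    stringsAsFactors = FALSE
  )
}

#' Construct an interaction table
#'
#' Asserted miRNA -> target edges with provenance; duplicates of the same
#' (miRNA, target, kind) are merged with site counts summed and sources
#' concatenated.
#'
#' @param mirna_id,target_id Character vectors.
#' @param target_kind `"circRNA"` or `"mRNA"` per row.
#' @param source Provenance tag per row.
#' @param n_sites Optional site count per row (default 1).
#' @return data.frame of class `interaction_table` with columns `mirna_id`,
#'   `target_id`, `target_kind`, `source`, `n_sites`, sorted.
#' @export
interaction_table <- function(mirna_id = character(0),
                              target_id = character(0),
                              target_kind = character(0),
                              source = "user",
                              n_sites = 1L) {
  n <- length(mirna_id)
  if (n > 0 && length(target_kind) == 1L) target_kind <- rep(target_kind, n)
  .stop_if(length(target_id) != n || (n > 0 && length(target_kind) != n),
           "mirna_id, target_id and target_kind must have equal length")
  .stop_if(n > 0 && !all(target_kind %in% c("circRNA", "mRNA")),
           "target_kind must be 'circRNA' or 'mRNA'")
  df <- data.frame(
    mirna_id = as.character(mirna_id),
    target_id = as.character(target_id),
    target_kind = as.character(target_kind),
    source = rep_len(as.character(source), n),
    n_sites = as.integer(rep_len(n_sites, n)),
    stringsAsFactors = FALSE
  )
  df <- .dedupe_interactions(df)
  class(df) <- c("interaction_table", "data.frame")
  df
}

.dedupe_interactions <- function(df) {
  if (nrow(df) == 0L) return(df)
  # a duplicated pair with two different kinds is a contract violation
  pair <- paste(df$mirna_id, df$target_id, sep = "\r")
  kinds <- tapply(df$target_kind, pair, function(k) length(unique(k)))
  .stop_if(any(kinds > 1),
           "conflicting target_kind for pair(s): ",
           paste(gsub("\r", " -> ", names(kinds)[kinds > 1]), collapse = ", "))
  key <- paste(df$mirna_id, df$target_id, df$target_kind, sep = "\r")
  agg_sites <- tapply(df$n_sites, key, sum)
  agg_src <- tapply(df$source, key, function(s)
    paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";"))
  keys <- sort(names(agg_sites))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    mirna_id = vapply(parts, `[`, "", 1L),
    target_id = vapply(parts, `[`, "", 2L),
    target_kind = vapply(parts, `[`, "", 3L),
    source = unname(agg_src[keys]),
    n_sites = as.integer(unname(agg_sites[keys])),
    stringsAsFactors = FALSE
  )
}

#' Predict miRNA -> target interactions by seed matching
#'
#' Scans every (miRNA, target) pair with [find_seed_matches()] and keeps
#' pairs with at least one site of at least `min_site_type` (hierarchy:
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer). A self-contained, deterministic
#' stand-in for external target-prediction databases; externally derived
#' tables can be merged in with [merge_interactions()].
#'
#' @param mirnas Named character vector of miRNA sequences (RNA 5'->3').
#' @param targets Named character vector of target sequences
#'   (transcript sense; supply 3'UTRs for mRNAs).
#' @param target_kind `"circRNA"` or `"mRNA"` for the whole target set.
#' @param min_site_type Weakest site type that still counts.
#' @return An [interaction_table()] with `source = "seed_match"` and
#'   `n_sites` the number of qualifying sites.
#' @export
predict_interactions <- function(mirnas, targets,
                                 target_kind = c("circRNA", "mRNA"),
                                 min_site_type = "7mer-A1") {
  target_kind <- match.arg(target_kind)
  .stop_if(!min_site_type %in% SITE_TYPES,
           "`min_site_type` must be one of: ", paste(SITE_TYPES, collapse = ", "))
  if (length(mirnas) == 0L || length(targets) == 0L) {
    return(interaction_table())
  }
  .stop_if(is.null(names(mirnas)) || is.null(names(targets)),
           "`mirnas` and `targets` must be named")
  keep_types <- SITE_TYPES[seq_len(match(min_site_type, SITE_TYPES))]
  rows <- list()
  for (m in names(mirnas)) {
    for (t in names(targets)) {
      hits <- find_seed_matches(mirnas[[m]], targets[[t]])
      n_ok <- sum(hits$site_type %in% keep_types)
      if (n_ok > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, target_id = t, target_kind = target_kind,
          source = "seed_match", n_sites = n_ok, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(interaction_table())
  df <- do.call(rbind, rows)
  interaction_table(df$mirna_id, df$target_id, df$target_kind,
                    df$source, df$n_sites)
}

#' Merge two interaction tables
#'
#' Union of predicted and loaded interactions with provenance retained:
#' duplicate (miRNA, target, kind) rows collapse to one row with sources
#' concatenated (`;`-joined, sorted, unique) and site counts summed. The
#' same pair annotated with two different target kinds is an error.
#'
#' @param predicted,loaded [interaction_table()] objects (or data.frames
#'   with the same columns).
#' @return A merged [interaction_table()].
#' @export
merge_interactions <- function(predicted, loaded) {
  cols <- c("mirna_id", "target_id", "target_kind", "source", "n_sites")
  both <- rbind(as.data.frame(predicted)[, cols, drop = FALSE],
                as.data.frame(loaded)[, cols, drop = FALSE])
  interaction_table(both$mirna_id, both$target_id, both$target_kind,
                    both$source, both$n_sites)
}
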