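# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the distribution shortcuts they use), so agreement is
# a genuine cross-check rather than a tautology.

oracle_random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# sliding-window seed matcher: string-compare every window of the target
# against the four canonical site definitions; keep the best type per start
oracle_seed_matches <- function(mirna, target) {
  seed7 <- oracle_revcomp(substr(mirna, 2, 8))
  seed6 <- oracle_revcomp(substr(mirna, 2, 7))
  defs <- c("8mer" = paste0(seed7, "A"), "7mer-m8" = seed7,
            "7mer-A1" = paste0(seed6, "A"), "6mer" = seed6)
  n <- nchar(target)
  rows <- list()
  seen <- integer(0)
  for (type in names(defs)) {
    pat <- defs[[type]]
    k <- nchar(pat)
    if (k > n) next
    for (i in seq_len(n - k + 1)) {
      if (substr(target, i, i + k - 1) == pat && !(i %in% seen)) {
        seen <- c(seen, i)
        rows[[length(rows) + 1]] <- data.frame(
          site_type = type, start = i - 1L, end = i - 1L + k,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  df
}

# direct tail summation of the conditional count distribution
# P(j | x) = (n2/n1)^j (x+j)! / (x! j! (1+n2/n1)^(x+j+1))
oracle_count_test <- function(x, y, n1, n2) {
  r <- n2 / n1
  logpmf <- function(j) {
    j * log(r) + lgamma(x + j + 1) - lgamma(x + 1) - lgamma(j + 1) -
      (x + j + 1) * log(1 + r)
  }
  lo <- sum(exp(vapply(0:y, logpmf, numeric(1))))
  # upper tail summed directly until the terms vanish (avoids 1 - lo
  # cancellation for tiny tails)
  hi <- 0
  j <- y + 1
  repeat {
    term <- exp(logpmf(j))
    hi <- hi + term
    j <- j + 1
    if ((term < hi * 1e-18 && j > y + 10) || j > y + 100000) break
  }
  min(1, 2 * min(lo, hi))
}

# exhaustive triplet enumeration over all (circ, miRNA, mRNA) combinations,
# filtered by the ceRNA invariants
oracle_triplets <- function(circ_groups, mirna_groups, mrna_groups,
                            interactions, group) {
  it <- as.data.frame(interactions)
  edge_keys <- paste(it$mirna_id, it$target_id, it$target_kind)
  combos <- expand.grid(circ_id = circ_groups$transcript_id,
                        mirna_id = mirna_groups$transcript_id,
                        mrna_id = mrna_groups$transcript_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lookup <- function(df, id, col) df[[col]][match(id, df$transcript_id)]
  keep <- vapply(seq_len(nrow(combos)), function(i) {
    cid <- combos$circ_id[i]; mid <- combos$mirna_id[i]
    gid <- combos$mrna_id[i]
    if (lookup(circ_groups, cid, "group") != group) return(FALSE)
    if (lookup(mirna_groups, mid, "group") != group) return(FALSE)
    if (lookup(mrna_groups, gid, "group") != group) return(FALSE)
    dc <- lookup(circ_groups, cid, "direction")
    dm <- lookup(mirna_groups, mid, "direction")
    dg <- lookup(mrna_groups, gid, "direction")
    if (is.na(dc) || is.na(dm) || is.na(dg)) return(FALSE)
    if (!(dc == dg && dc != dm)) return(FALSE)
    paste(mid, cid, "circRNA") %in% edge_keys &&
      paste(mid, gid, "mRNA") %in% edge_keys
  }, logical(1))
  out <- combos[keep, c("circ_id", "mirna_id", "mrna_id")]
  out <- out[order(out$circ_id, out$mirna_id, out$mrna_id), ]
  rownames(out) <- NULL
  out
}

# exhaustive hypergeometric enumeration: fraction of all C(N, n) query
# draws with at least k members of the first K background genes
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# literal Benjamini-Hochberg step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m / seq_len(m) * p[o])
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# random exclusive-group tables and interaction tables for triplet testing
random_group_table <- function(prefix, n) {
  grp <- sample(exclusive_groups(), n, replace = TRUE)
  data.frame(
    transcript_id = paste0(prefix, seq_len(n)),
    group = grp,
    direction = ifelse(grp == "none", NA_character_,
                       sample(c("up", "down"), n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

random_triplet_instance <- function(n_circ, n_mirna, n_mrna, p_edge = 0.3) {
  circ <- random_group_table("C", n_circ)
  mir <- random_group_table("M", n_mirna)
  mrna <- random_group_table("G", n_mrna)
  pairs_c <- expand.grid(mirna_id = mir$transcript_id,
                         target_id = circ$transcript_id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs_g <- expand.grid(mirna_id = mir$transcript_id,
                         target_id = mrna$transcript_id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs_c <- pairs_c[stats::runif(nrow(pairs_c)) < p_edge, , drop = FALSE]
  pairs_g <- pairs_g[stats::runif(nrow(pairs_g)) < p_edge, , drop = FALSE]
  ints <- interaction_table(
    c(pairs_c$mirna_id, pairs_g$mirna_id),
    c(pairs_c$target_id, pairs_g$target_id),
    c(rep("circRNA", nrow(pairs_c)), rep("mRNA", nrow(pairs_g))))
  list(circ = circ, mir = mir, mrna = mrna, interactions = ints)
}
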