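mk_de <- function(id, de_in, dirs) {
  comps <- adjacent_comparisons()$label
  data.frame(
    transcript_id = id,
    comparison = comps,
    direction = ifelse(comps %in% de_in, dirs[comps], "none"),
    is_de = comps %in% de_in,
    stringsAsFactors = FALSE)
}

test_that("exclusive groups follow the one-comparison-only rule", {
  dirs <- c(PreVsPro = "up", ImmatureVsPre = "down", MatureVsImmature = "up")
  de <- rbind(
    mk_de("a", "PreVsPro", dirs),
    mk_de("b", c("PreVsPro", "MatureVsImmature"), dirs),
    mk_de("c", character(0), dirs),
    mk_de("d", "MatureVsImmature", dirs))
  g <- assign_exclusive_groups(de)
  expect_equal(g$group[g$transcript_id == "a"], "PrePro_only")
  expect_equal(g$direction[g$transcript_id == "a"], "up")
  expect_equal(g$group[g$transcript_id == "b"], "none")
  expect_equal(g$group[g$transcript_id == "c"], "none")
  expect_equal(g$group[g$transcript_id == "d"], "MatureImmature_only")
  expect_error(assign_exclusive_groups(de[-1, ]), "missing a comparison")
})

test_that("random DE tables match brute-force truth-table evaluation", {
  set.seed(23)
  comps <- adjacent_comparisons()$label
  for (rep in 1:10) {
    ids <- paste0("t", 1:30)
    de <- do.call(rbind, lapply(ids, function(id) {
      is_de <- runif(3) < 0.4
      dir <- ifelse(is_de, sample(c("up", "down"), 3, TRUE), "none")
      data.frame(transcript_id = id, comparison = comps,
                 direction = dir, is_de = is_de, stringsAsFactors = FALSE)
    }))
    g <- assign_exclusive_groups(de)
    for (id in ids) {
      sub <- de[de$transcript_id == id, ]
      want <- if (sum(sub$is_de) == 1) {
        c(PreVsPro = "PrePro_only", ImmatureVsPre = "ImmaturePre_only",
          MatureVsImmature = "MatureImmature_only")[[sub$comparison[sub$is_de]]]
      } else "none"
      expect_equal(g$group[g$transcript_id == id], want)
    }
  }
})

test_that("a single direction-consistent triplet is emitted and scheme violations are not", {
  circ <- data.frame(transcript_id = "C1", group = "PrePro_only",
                     direction = "down", stringsAsFactors = FALSE)
  mir <- data.frame(transcript_id = "M1", group = "PrePro_only",
                    direction = "up", stringsAsFactors = FALSE)
  mrna_dn <- data.frame(transcript_id = "G1", group = "PrePro_only",
                        direction = "down", stringsAsFactors = FALSE)
  ints <- interaction_table(c("M1", "M1"), c("C1", "G1"),
                            c("circRNA", "mRNA"))
  got <- build_triplets(circ, mir, mrna_dn, ints, "PrePro_only")
  expect_equal(nrow(got), 1)
  expect_equal(got$circ_id, "C1")
  expect_equal(got$scheme, "circ_down_mir_up_mrna_down")

  mrna_up <- transform(mrna_dn, direction = "up")
  expect_equal(nrow(build_triplets(circ, mir, mrna_up, ints, "PrePro_only")), 0)
  expect_error(build_triplets(circ, mir, mrna_dn, ints, "NoSuchGroup"),
               "unknown group")
})

test_that("the four-miRNA sponge hub around one mRNA is reconstructed", {
  # one upregulated circRNA sponging four downregulated miRNAs that all
  # target one upregulated mRNA (complement receptor 2), all exclusive to
  # the immature->mature transition
  mirs <- c("mmu-miR-130b-5p", "mmu-miR-148a-5p", "mmu-miR-18b-3p",
            "mmu-miR-467e-5p")
  circ <- data.frame(transcript_id = "novel_circ_000150",
                     group = "MatureImmature_only", direction = "up",
                     stringsAsFactors = FALSE)
  mir <- data.frame(transcript_id = mirs, group = "MatureImmature_only",
                    direction = "down", stringsAsFactors = FALSE)
  mrna <- data.frame(transcript_id = "Cr2", group = "MatureImmature_only",
                     direction = "up", stringsAsFactors = FALSE)
  ints <- interaction_table(
    rep(mirs, each = 2),
    rep(c("novel_circ_000150", "Cr2"), 4),
    rep(c("circRNA", "mRNA"), 4))
  got <- build_triplets(circ, mir, mrna, ints, "MatureImmature_only")
  expect_equal(nrow(got), 4)
  expect_equal(unique(got$mrna_id), "Cr2")
  expect_equal(sort(got$mirna_id), sort(mirs))
  expect_equal(unique(got$scheme), "circ_up_mir_down_mrna_up")
  s <- network_summary(got)
  expect_equal(s, list(n_circ = 1L, n_mirna = 4L, n_mrna = 1L, n_edges = 8L))
})

test_that("triplet assembly equals exhaustive enumeration on random instances", {
  set.seed(33)
  for (rep in 1:8) {
    inst <- random_triplet_instance(sample(3:8, 1), sample(3:8, 1),
                                    sample(3:8, 1))
    for (grp in setdiff(exclusive_groups(), "none")) {
      got <- build_triplets(inst$circ, inst$mir, inst$mrna,
                            inst$interactions, grp)
      want <- oracle_triplets(inst$circ, inst$mir, inst$mrna,
                              inst$interactions, grp)
      expect_equal(got[, c("circ_id", "mirna_id", "mrna_id")], want)
      # per-triplet direction consistency
      if (nrow(got) > 0) {
        dir_of <- function(df, id) df$direction[match(id, df$transcript_id)]
        for (i in seq_len(nrow(got))) {
          dc <- dir_of(inst$circ, got$circ_id[i])
          dm <- dir_of(inst$mir, got$mirna_id[i])
          dg <- dir_of(inst$mrna, got$mrna_id[i])
          expect_true(dc == dg && dc != dm)
        }
      }
    }
  }
})

test_that("network summary counts distinct ids and de-duplicated edges", {
  empty <- build_triplets(
    data.frame(transcript_id = character(0), group = character(0),
               direction = character(0), stringsAsFactors = FALSE),
    data.frame(transcript_id = character(0), group = character(0),
               direction = character(0), stringsAsFactors = FALSE),
    data.frame(transcript_id = character(0), group = character(0),
               direction = character(0), stringsAsFactors = FALSE),
    interaction_table(), "PrePro_only")
  expect_equal(network_summary(empty),
               list(n_circ = 0L, n_mirna = 0L, n_mrna = 0L, n_edges = 0L))

  set.seed(34)
  tri <- data.frame(
    circ_id = sample(paste0("C", 1:4), 20, TRUE),
    mirna_id = sample(paste0("M", 1:3), 20, TRUE),
    mrna_id = sample(paste0("G", 1:5), 20, TRUE),
    group = "PrePro_only", scheme = "circ_down_mir_up_mrna_down",
    stringsAsFactors = FALSE)
  s <- network_summary(tri)
  expect_equal(s$n_circ, length(unique(tri$circ_id)))
  expect_equal(s$n_edges,
               length(unique(paste(tri$circ_id, tri$mirna_id))) +
                 length(unique(paste(tri$mirna_id, tri$mrna_id))))
})
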