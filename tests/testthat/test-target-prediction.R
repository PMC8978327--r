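mir <- "UAAGGCACGCGGUGAAUGCC"  # seed (nt 2-8) AAGGCAC -> site core GUGCCUU

test_that("the canonical 8mer site is found at its forced position", {
  target <- paste0("CCCC", "GUGCCUUA", "GGGG")
  hits <- find_seed_matches(mir, target)
  expect_true(any(hits$site_type == "8mer" & hits$start == 4 & hits$end == 12))
})

test_that("a target without a complementary run yields no sites", {
  expect_equal(nrow(find_seed_matches(mir, "CCCCCCCCCCCCCCCCCC")), 0)
})

test_that("sequence validation reports offending characters and short miRNAs", {
  expect_error(find_seed_matches(mir, "ACGTACG"), "position 4")
  expect_error(find_seed_matches("ACGUACN", "ACGU"), "position 7")
  expect_error(find_seed_matches("ACGUACG", "ACGUACGU"), "at least 8")
})

test_that("matcher equals the sliding-window oracle on random pairs", {
  set.seed(77)
  for (i in 1:60) {
    m <- oracle_random_rna(sample(18:24, 1))
    t <- oracle_random_rna(sample(15:120, 1))
    expect_identical(find_seed_matches(m, t), oracle_seed_matches(m, t))
  }
})

test_that("predictions respect the minimum site type and its hierarchy", {
  # core UGCCUU placed so that no A follows and no comp(m8)=G precedes:
  # the pair has a 6mer site and nothing better
  target <- paste0("CC", "UGCCUU", "C", "GGGG")
  hits <- find_seed_matches(mir, target)
  expect_equal(hits$site_type, "6mer")
  tab6 <- predict_interactions(c(m1 = mir), c(t1 = target),
                               "mRNA", min_site_type = "6mer")
  expect_equal(nrow(tab6), 1)
  tab8 <- predict_interactions(c(m1 = mir), c(t1 = target),
                               "mRNA", min_site_type = "8mer")
  expect_equal(nrow(tab8), 0)
  expect_error(predict_interactions(c(m1 = mir), c(t1 = target),
                                    "mRNA", min_site_type = "5mer"),
               "min_site_type")
})

test_that("relaxing the minimum site type never removes an interaction", {
  set.seed(78)
  mirnas <- stats::setNames(replicate(5, oracle_random_rna(21)),
                            paste0("m", 1:5))
  targets <- stats::setNames(replicate(8, oracle_random_rna(150)),
                             paste0("t", 1:8))
  prev <- NULL
  for (ty in c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    tab <- predict_interactions(mirnas, targets, "mRNA", min_site_type = ty)
    keys <- paste(tab$mirna_id, tab$target_id)
    if (!is.null(prev)) expect_true(all(prev %in% keys))
    prev <- keys
  }
})

test_that("empty miRNA or target sets give an empty table, not an error", {
  expect_equal(nrow(predict_interactions(character(0), c(t = "ACGU"), "mRNA")), 0)
  expect_equal(nrow(predict_interactions(c(m = mir), character(0), "mRNA")), 0)
})

test_that("merging keeps provenance and collapses duplicates", {
  a <- interaction_table("m1", "t1", "circRNA", source = "seed_match")
  expect_identical(merge_interactions(a, interaction_table()), a)
  b <- interaction_table("m1", "t1", "circRNA", source = "starbase")
  ab <- merge_interactions(a, b)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$source, "seed_match;starbase")
  expect_equal(ab$n_sites, 2L)
  conflicting <- interaction_table("m1", "t1", "mRNA")
  expect_error(merge_interactions(a, conflicting), "conflicting target_kind")
})

test_that("merged row set equals the brute-force key union", {
  set.seed(79)
  mk <- function(n) interaction_table(
    sample(paste0("m", 1:4), n, TRUE), sample(paste0("t", 1:6), n, TRUE),
    "mRNA", source = sample(c("a", "b"), n, TRUE))
  x <- mk(12); y <- mk(12)
  merged <- merge_interactions(x, y)
  want <- sort(unique(c(paste(x$mirna_id, x$target_id),
                        paste(y$mirna_id, y$target_id))))
  expect_equal(paste(merged$mirna_id, merged$target_id), want)
})

test_that("generated sequences contain planted 8mers exactly where recorded", {
  planted <- data.frame(mirna_id = c("m1", "m2"), target_id = c("t1", "t1"),
                        stringsAsFactors = FALSE)
  gs <- generate_sequences(c("m1", "m2"), c("t1", "t2"), planted,
                           rng_seed = 5, target_length = 120)
  for (i in seq_len(nrow(gs$sites))) {
    s <- gs$sites[i, ]
    site <- substr(gs$sequences[[s$target_id]], s$start + 1, s$end)
    seed7 <- oracle_revcomp(substr(gs$sequences[[s$mirna_id]], 2, 8))
    expect_identical(site, paste0(seed7, "A"))
  }
  # the non-planted target has no site for any miRNA
  for (m in c("m1", "m2")) {
    expect_equal(nrow(find_seed_matches(gs$sequences[[m]],
                                        gs$sequences[["t2"]])), 0)
  }
  expect_error(generate_sequences("m1", "t1", mirna_length = 6), "at least 8")
})

test_that("non-planted random pairs carry no seed sites at all", {
  gs <- generate_sequences(paste0("m", 1:10), paste0("t", 1:10),
                           rng_seed = 7, target_length = 150)
  for (m in paste0("m", 1:10)) {
    for (t in paste0("t", 1:10)) {
      expect_equal(nrow(find_seed_matches(gs$sequences[[m]],
                                          gs$sequences[[t]])), 0)
    }
  }
})
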