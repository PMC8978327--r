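test_that("configuration bounds are validated with the violated bound named", {
  expect_error(simulation_config(n_circ = -1), "nonnegative integer")
  expect_error(simulation_config(frac_stage_specific = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_circ = 3, n_mirna = 3, n_mrna = 3,
                                 n_planted_triplets = 5),
               "exceeds min")
  expect_error(simulation_config(pattern_labels = "up-sideways-down"),
               "unknown pattern label")
  expect_error(simulation_config(de_fold_change = 0.5), "> 1")
  expect_error(simulation_config(sequencing_depth = c(1e6, 1e6)),
               "scalar or length 4")
  expect_error(simulation_config(mirna_length = 5), "at least 8")
})

test_that("an all-zero configuration yields empty matrices and empty truth", {
  res <- generate_dataset(simulation_config(
    n_circ = 0, n_mirna = 0, n_mrna = 0, n_planted_patterns = 0,
    n_planted_de = 0, n_planted_triplets = 0, with_sequences = FALSE))
  expect_equal(nrow(res$dataset$circ), 0)
  expect_equal(nrow(res$dataset$mrna_counts), 0)
  expect_equal(nrow(res$truth$de_truth), 0)
  expect_equal(nrow(res$truth$planted_triplets), 0)
  expect_length(res$truth$pattern_labels, 0)
})

test_that("identical config and seed reproduce the dataset bit-identically", {
  cfg <- simulation_config(n_circ = 80, n_mirna = 60, n_mrna = 100,
                           frac_stage_specific = 0.3, n_planted_patterns = 1,
                           n_planted_de = 2, n_planted_triplets = 2,
                           rng_seed = 101)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  cfg2 <- simulation_config(n_circ = 80, n_mirna = 60, n_mrna = 100,
                            frac_stage_specific = 0.3, n_planted_patterns = 1,
                            n_planted_de = 2, n_planted_triplets = 2,
                            rng_seed = 102)
  expect_false(identical(generate_dataset(cfg2), a))
})

test_that("normalized layers follow their stated unit formulas", {
  cfg <- simulation_config(n_circ = 50, n_mirna = 40, n_mrna = 60,
                           frac_stage_specific = 0.3, n_planted_patterns = 0,
                           n_planted_de = 0, n_planted_triplets = 0,
                           with_sequences = FALSE, rng_seed = 103)
  res <- generate_dataset(cfg)
  ds <- res$dataset
  lib <- ds$lib_sizes
  expect_equal(unname(unclass(ds$circ)[, ]),
               unname(sweep(ds$circ_counts, 2, lib, "/") * 1e6))
  expect_equal(unname(unclass(ds$mirna)[, ]),
               unname(sweep(ds$mirna_counts, 2, lib, "/") * 1e6))
  len <- ds$mrna_lengths[rownames(ds$mrna_counts)]
  want_fpkm <- ds$mrna_counts / outer(len / 1e3, lib / 1e6)
  expect_equal(unname(unclass(ds$mrna)[, ]), unname(want_fpkm))
  expect_true(all(len >= 500 & len <= 5000))
  expect_true(all(ds$circ_counts >= 0) && all(ds$circ_counts == floor(ds$circ_counts)))
})

test_that("hard planting makes specificity recovery exact in every layer", {
  cfg <- simulation_config(n_circ = 200, n_mirna = 150, n_mrna = 200,
                           frac_stage_specific = c(0.6, 0.1, 0.1),
                           n_planted_patterns = 1, n_planted_de = 2,
                           n_planted_triplets = 2, hard_planting = TRUE,
                           rng_seed = 104)
  res <- generate_dataset(cfg)
  for (layer in c("circ", "mirna", "mrna")) {
    mat <- res$dataset[[layer]]
    got <- call_expressed(mat)
    expect_identical(unname(got), unname(res$truth$expressed[[layer]]))
    calls <- classify_specificity(got)
    spec_got <- ifelse(calls$is_stage_specific, calls$class, NA_character_)
    expect_identical(spec_got, unname(res$truth$specific_stage[[layer]]))
  }
})

test_that("planted triplet truth satisfies its own invariants", {
  cfg <- simulation_config(n_circ = 100, n_mirna = 80, n_mrna = 120,
                           frac_stage_specific = 0.2, n_planted_patterns = 0,
                           n_planted_de = 0, n_planted_triplets = 4,
                           hard_planting = TRUE, rng_seed = 105)
  res <- generate_dataset(cfg)
  tri <- res$truth$planted_triplets
  expect_equal(nrow(tri), 12)  # 4 per comparison group
  de <- res$truth$de_truth
  dir_of <- function(layer, id, comp) {
    de$direction[de$layer == layer & de$transcript_id == id &
                   de$comparison == comp]
  }
  for (i in seq_len(nrow(tri))) {
    dc <- dir_of("circ", tri$circ_id[i], tri$comparison[i])
    dm <- dir_of("mirna", tri$mirna_id[i], tri$comparison[i])
    dg <- dir_of("mrna", tri$mrna_id[i], tri$comparison[i])
    expect_true(dc == dg && dc != dm)
    # DE in exactly one comparison
    for (layer_id in list(c("circ", tri$circ_id[i]),
                          c("mirna", tri$mirna_id[i]),
                          c("mrna", tri$mrna_id[i]))) {
      sub <- de[de$layer == layer_id[1] & de$transcript_id == layer_id[2], ]
      expect_equal(sum(sub$direction != "null"), 1)
    }
  }
  # every planted pair has a recorded 8mer on both partners
  sites <- res$truth$planted_sites
  for (i in seq_len(nrow(tri))) {
    expect_true(any(sites$mirna_id == tri$mirna_id[i] &
                      sites$target_id == tri$circ_id[i]))
    expect_true(any(sites$mirna_id == tri$mirna_id[i] &
                      sites$target_id == tri$mrna_id[i]))
  }
})

test_that("negative-binomial noise and pooled replicates are supported", {
  cfg <- simulation_config(n_circ = 60, n_mirna = 30, n_mrna = 40,
                           frac_stage_specific = 0.3, n_planted_patterns = 0,
                           n_planted_de = 0, n_planted_triplets = 0,
                           noise_model = "negative_binomial", dispersion = 0.2,
                           replicates_per_stage = 3, with_sequences = FALSE,
                           rng_seed = 106)
  res <- generate_dataset(cfg)
  expect_true(all(res$dataset$circ_counts >= 0))
  expect_equal(unname(res$dataset$lib_sizes), rep(3e6, 4))
  # library scaling keeps the per-million normalization consistent
  expect_equal(unname(unclass(res$dataset$circ)[, ]),
               unname(sweep(res$dataset$circ_counts, 2,
                            res$dataset$lib_sizes, "/") * 1e6))
})

test_that("stochastic stage-specific fraction stays near the planted rate", {
  fr <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_circ = 300, n_mirna = 0, n_mrna = 0,
                             frac_stage_specific = 0.6, n_planted_patterns = 0,
                             n_planted_de = 0, n_planted_triplets = 0,
                             with_sequences = FALSE, rng_seed = s)
    res <- generate_dataset(cfg)
    calls <- classify_specificity(call_expressed(res$dataset$circ))
    expressed <- calls$class != "not_expressed"
    mean(calls$is_stage_specific[expressed])
  }, numeric(1))
  expect_true(all(fr > 0.45 & fr < 0.75))
})
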