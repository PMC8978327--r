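stages <- b_cell_stages()

mk_matrix <- function(values, ids = NULL) {
  m <- matrix(values, ncol = 4, byrow = TRUE,
              dimnames = list(ids %||% paste0("t", seq_len(length(values) / 4)),
                              stages))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("expressed calls follow the threshold boundary rules", {
  m <- mk_matrix(rep(0, 8))
  expect_false(any(call_expressed(m, 0)))

  m2 <- mk_matrix(c(1, 0.999, 1.001, 0))
  expect_equal(unname(call_expressed(m2, 1)[1, ]), c(TRUE, FALSE, TRUE, FALSE))
  # threshold 0 means strictly positive
  expect_equal(unname(call_expressed(m2, 0)[1, ]), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(call_expressed(m2, -1), "nonnegative")
})

test_that("expressed calls agree with cell-wise brute force on random data", {
  set.seed(11)
  m <- mk_matrix(round(runif(200 * 4, 0, 3), 2))
  for (thr in c(0, 0.5, 1)) {
    got <- call_expressed(m, thr)
    want <- m
    for (i in seq_len(nrow(m))) {
      for (j in 1:4) {
        want[i, j] <- if (thr > 0) m[i, j] >= thr else m[i, j] > 0
      }
    }
    expect_identical(got, want == 1)
  }
})

test_that("specificity classes are the exact expressed-stage subsets", {
  m <- mk_matrix(c(5, 0, 0, 0,
                   1, 1, 1, 1,
                   0, 0, 0, 0,
                   0, 2, 0, 2))
  calls <- classify_specificity(call_expressed(m))
  expect_equal(calls$class,
               c("pro-B", "pro-B+pre-B+immature+mature", "not_expressed",
                 "pre-B+mature"))
  expect_equal(calls$is_stage_specific, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("Venn class counts match brute-force subset enumeration and sum to n", {
  set.seed(42)
  ex <- matrix(runif(200 * 4) < 0.5, 200, 4,
               dimnames = list(paste0("t", 1:200), stages))
  counts <- venn_counts(ex)
  expect_equal(sum(counts), 200L)
  # brute force: count each of the 16 subsets directly
  for (cls in names(counts)) {
    if (cls == "not_expressed") {
      want <- sum(rowSums(ex) == 0)
    } else {
      sub <- strsplit(cls, "+", fixed = TRUE)[[1]]
      flags <- stages %in% sub
      want <- sum(apply(ex, 1, function(r) all(r == flags)))
    }
    expect_equal(unname(counts[cls]), want)
  }
})

test_that("stage-specific counts are invariant to stage relabelling", {
  set.seed(5)
  ex <- matrix(runif(100 * 4) < 0.4, 100, 4,
               dimnames = list(paste0("t", 1:100), stages))
  perm <- c(3, 1, 4, 2)
  ex_perm <- ex[, perm]
  colnames(ex_perm) <- stages  # relabel back to canonical order
  calls <- classify_specificity(ex)
  calls_perm <- classify_specificity(ex_perm)
  for (s in seq_along(stages)) {
    n1 <- sum(calls$class == stages[perm[s]])
    n2 <- sum(calls_perm$class == stages[s])
    expect_equal(n1, n2)
  }
})

test_that("specificity fraction handles arithmetic and degenerate cases", {
  ex <- matrix(FALSE, 10, 4, dimnames = list(paste0("t", 1:10), stages))
  ex[1:6, 1] <- TRUE                   # six pro-B-specific
  ex[7:10, 1] <- TRUE; ex[7:10, 2] <- TRUE  # four shared pro-B/pre-B
  calls <- classify_specificity(ex)
  expect_equal(specificity_fraction(calls, "pro-B"), 0.6)
  expect_true(is.na(specificity_fraction(calls, "mature")))
  expect_error(specificity_fraction(calls, "plasma"), "unknown stage")
})

test_that("stage correlation matches the direct Pearson formula", {
  m <- mk_matrix(c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(unname(stage_correlation(m)), matrix(1, 4, 4))

  two <- matrix(c(0, 4, 4, 0), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(stage_correlation(two)[1, 2]), -1)

  set.seed(9)
  r50 <- mk_matrix(runif(50 * 4, 0, 100))
  got <- stage_correlation(r50)
  for (i in 1:4) for (j in 1:4) {
    x <- r50[, i]; y <- r50[, j]
    want <- sum((x - mean(x)) * (y - mean(y))) /
      (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
    expect_equal(got[i, j], want, tolerance = 1e-12)
  }
  expect_true(isSymmetric(got))
  expect_equal(unname(diag(got)), rep(1, 4))
})

test_that("zero-variance stages are flagged as undefined, not zero", {
  m <- mk_matrix(c(1, 2, 0, 5,
                   3, 1, 0, 2))
  expect_warning(r <- stage_correlation(m), "zero-variance")
  expect_true(all(is.na(r["immature", setdiff(stages, "immature")])))
  expect_equal(r["immature", "immature"], 1)
  expect_error(stage_correlation(m[1, , drop = FALSE]), "at least 2")
})
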