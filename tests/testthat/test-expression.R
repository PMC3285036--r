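test_that("missingness filter keeps genes at or below the threshold", {
  set.seed(1)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  # genes with 0, 1, 2, 3, 4 missing entries out of 10
  for (i in 2:5) m[i, seq_len(i - 1)] <- NA
  em <- expression_matrix(m, setNames(rep(c("cancer", "normal"), 5),
                                      paste0("s", 1:10)))
  kept <- filter_genes_by_missingness(em, 0.2)
  expect_identical(rownames(kept$values), c("g1", "g2", "g3"))  # <= 20% kept
  expect_identical(colnames(kept$values), colnames(m))

  # gene with 3/10 missing is removed, gene with none is retained
  expect_false("g4" %in% rownames(kept$values))
  expect_true("g1" %in% rownames(kept$values))

  # idempotent
  twice <- filter_genes_by_missingness(kept, 0.2)
  expect_identical(twice$values, kept$values)

  m_all <- m
  m_all[1, 1] <- NA   # now every gene has at least one missing entry
  em_all <- expression_matrix(m_all, em$condition)
  expect_warning(filter_genes_by_missingness(em_all, 0), "all genes removed")
  empty <- suppressWarnings(filter_genes_by_missingness(em_all, 0))
  expect_identical(nrow(empty$values), 0L)
})

test_that("KNN imputation matches the brute-force oracle and preserves observed data", {
  em0 <- rand_em(20, 4, 4, seed = 42)
  expect_identical(knn_impute(em0, 3)$values, em0$values)  # nothing missing

  em <- rand_em(20, 4, 4, seed = 42, missing = 0.05)
  imp <- knn_impute(em, 3)
  expect_false(anyNA(imp$values))
  obs <- !is.na(em$values)
  expect_identical(imp$values[obs], em$values[obs])
  expect_equal(imp$values, brute_knn_impute(em$values, 3), tolerance = 1e-9)

  # k = 1 with an identical-profile neighbour copies its value
  m <- rbind(g1 = c(1, 2, 3, NA), g2 = c(1, 2, 3, 9), g3 = c(5, -1, 0, 2))
  colnames(m) <- paste0("s", 1:4)
  em2 <- expression_matrix(m, setNames(c("cancer", "cancer", "normal",
                                         "normal"), paste0("s", 1:4)))
  expect_equal(knn_impute(em2, 1)$values["g1", "s4"], 9)

  # k beyond the neighbour pool falls back with a warning
  expect_warning(knn_impute(em2, 10), "fewer than k")

  # a gene missing everywhere should have been filtered
  m[1, ] <- NA
  em3 <- expression_matrix(m, em2$condition)
  expect_error(knn_impute(em3, 1), "every sample")
})

test_that("condition means are plain arithmetic means per group", {
  m <- rbind(g1 = c(1, 3, 10), g2 = c(0, -2, 7))
  colnames(m) <- c("c1", "c2", "n1")
  em <- expression_matrix(m, c(c1 = "cancer", c2 = "cancer", n1 = "normal"))
  expect_equal(condition_mean(em, "g1", "cancer"), 2)
  expect_equal(condition_mean(em, "g1", "normal"), 10)   # single sample

  em10 <- rand_em(3, 10, 2, seed = 5)
  x <- em10$values["g01", em10$condition == "cancer"]
  expect_equal(condition_mean(em10, "g01", "cancer"), sum(x) / 10,
               tolerance = 1e-12)
  expect_error(condition_mean(em, "nope", "cancer"), "unknown gene")
})

test_that("cancer-sample Pearson correlation has the standard closed form", {
  m <- rbind(g1 = c(1, 2, 3, 4, 0), g2 = c(2, 4, 5, 9, 99),
             g3 = c(-1, -2, -3, -4, 1), g4 = c(7, 7, 7, 7, 0))
  colnames(m) <- c(paste0("c", 1:4), "n1")
  cond <- setNames(c(rep("cancer", 4), "normal"), colnames(m))
  em <- expression_matrix(m, cond)

  expect_equal(pearson_cancer(em, "g1", "g1"), 1)   # identical profiles
  expect_equal(pearson_cancer(em, "g1", "g3"), -1)  # negated profile
  expect_equal(pearson_cancer(em, "g1", "g2"),
               pearson_oracle(c(1, 2, 3, 4), c(2, 4, 5, 9)),
               tolerance = 1e-12)
  expect_identical(pearson_cancer(em, "g1", "g4"), 0)  # zero variance

  # symmetry, affine invariance under positive scale, bounded by 1
  set.seed(9)
  for (i in 1:10) {
    em2 <- rand_em(4, 6, 2, seed = i)
    r <- pearson_cancer(em2, "g01", "g02")
    expect_equal(r, pearson_cancer(em2, "g02", "g01"))
    expect_lte(abs(r), 1)
    shifted <- em2
    shifted$values["g01", ] <- 3.7 * shifted$values["g01", ] - 2
    expect_equal(pearson_cancer(shifted, "g01", "g02"), r,
                 tolerance = 1e-9)
  }
  em_small <- expression_matrix(m[, c(1, 5)],
                                cond[c(1, 5)])
  expect_error(pearson_cancer(em_small, "g1", "g2"), "2 cancer samples")
})

test_that("Welch t statistic follows the textbook formula, cancer minus normal", {
  m <- rbind(same = rep(c(1, 5, 9), 2), up = c(5, 5, 5, 1, 1, 1))
  colnames(m) <- paste0("s", 1:6)
  cond <- setNames(rep(c("cancer", "normal"), each = 3), colnames(m))
  em <- expression_matrix(m, cond)
  expect_identical(ttest_statistic(em, "same"), 0)
  t_up <- ttest_statistic(em, "up")      # zero variance, nonzero difference
  expect_true(is.finite(t_up) && t_up > 1e6)

  set.seed(11)
  for (i in 1:10) {
    em2 <- rand_em(2, 7, 5, seed = 100 + i)
    x <- em2$values["g01", em2$condition == "cancer"]
    y <- em2$values["g01", em2$condition == "normal"]
    expect_equal(ttest_statistic(em2, "g01"), welch_oracle(x, y),
                 tolerance = 1e-9)
  }
})

test_that("expression matrix construction validates its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(m, c(s1 = "cancer", s2 = "normal")),
               "duplicate gene")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(m2, c(s1 = "cancer")), "without a condition")
  expect_error(expression_matrix(m2, c(s1 = "cancer", s2 = "weird")),
               "cancer")
})
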