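test_that("masked feature sets union thresholded component masks", {
  set.seed(71)
  L <- 300
  S <- laplace_sources(3, L)
  X <- matrix(rnorm(20 * L), 20, L)
  stats <- data.frame(component = 1:3, p = c(0.001, 0.4, 0.01),
                      significant = c(TRUE, FALSE, TRUE))
  fs <- build_masked_features(X, stats, S, tau = 2.5)
  manual <- sort(union(threshold_mask(component_zmap(S[1, ]), 2.5),
                       threshold_mask(component_zmap(S[3, ]), 2.5)))
  expect_equal(fs$voxel_idx, manual)
  expect_equal(dim(fs$data), c(20L, length(manual)))
  expect_equal(fs$data, X[, manual])
  expect_equal(fs$components, c(1L, 3L))

  # top_k picks the smallest p among significant components
  stats2 <- data.frame(component = 1:3, p = c(0.001, 0.04, 0.01),
                       significant = c(TRUE, TRUE, TRUE))
  fs2 <- build_masked_features(X, stats2, S, tau = 2.5, top_k = 2)
  expect_equal(fs2$components, c(1L, 3L))

  none <- data.frame(component = 1:3, p = rep(0.5, 3),
                     significant = rep(FALSE, 3))
  expect_error(build_masked_features(X, none, S), "no discriminative")
  expect_error(build_masked_features(X, stats, S, tau = 1e9), "lower tau")
})

test_that("combination enumeration covers all non-empty subsets", {
  combos <- enumerate_combinations(c("ALFF", "FA", "GM"))
  expect_length(combos, 7)
  sizes <- vapply(combos, length, 1L)
  expect_equal(as.integer(table(sizes)), c(3L, 3L, 1L))
  expect_length(enumerate_combinations("GM"), 1)
  expect_length(enumerate_combinations(c("a", "b")), 3)
  expect_error(enumerate_combinations(character(0)), "modalities")
})

test_that("well-separated classes are classified nearly perfectly", {
  set.seed(72)
  n <- 60; v <- 20
  X <- rbind(matrix(rnorm(n / 2 * v), n / 2, v),
             matrix(rnorm(n / 2 * v, mean = 6 / sqrt(v) * 2), n / 2, v))
  groups <- rep(c("HC", "SZ"), each = n / 2)
  fs <- structure(list(modality = "sim", data = X, voxel_idx = seq_len(v),
                       components = 1L, tau = 3.5),
                  class = "masked_feature_set")
  rep_ <- run_classification(list(fs), groups, n_repetitions = 25,
                             seed = 11, cv_folds = 5)
  expect_true(all(rep_$summary$mean_accuracy >= 0.95))
  expect_true(all(rep_$summary$max_accuracy >= rep_$summary$mean_accuracy))
})

test_that("reports are reproducible and carry the paired-split design", {
  set.seed(73)
  X1 <- matrix(rnorm(40 * 6), 40, 6)
  X2 <- matrix(rnorm(40 * 4), 40, 4)
  groups <- rep(c("a", "b"), each = 20)
  fs <- list(structure(list(modality = "m1", data = X1), class = "masked_feature_set"),
             structure(list(modality = "m2", data = X2), class = "masked_feature_set"))
  r1 <- run_classification(fs, groups, algorithms = c("linear-SVM", "kNN"),
                           n_repetitions = 8, seed = 4, cv_folds = 3)
  r2 <- run_classification(fs, groups, algorithms = c("linear-SVM", "kNN"),
                           n_repetitions = 8, seed = 4, cv_folds = 3)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$accuracies, r2$accuracies)
  # 2 modalities -> 3 combinations, each with both algorithms
  expect_equal(nrow(r1$summary), 3 * 2)
  expect_equal(sort(unique(r1$summary$combination)), c("m1", "m1+m2", "m2"))
})

test_that("label permutation drives accuracy to chance", {
  set.seed(74)
  X <- matrix(rnorm(40 * 8), 40, 8)
  groups <- sample(rep(c("a", "b"), each = 20))
  fs <- list(structure(list(modality = "m", data = X),
                       class = "masked_feature_set"))
  rep_ <- run_classification(fs, groups, algorithms = "linear-SVM",
                             n_repetitions = 40, seed = 9, cv_folds = 3)
  expect_lt(abs(rep_$summary$mean_accuracy - 0.5), 0.1)
})
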