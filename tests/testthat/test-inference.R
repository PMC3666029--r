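test_that("pooled two-sample t matches its analytic contract", {
  set.seed(61)
  A <- matrix(rnorm(63 * 3), 63, 3)
  groups <- rep(c("HC", "SZ"), c(28, 35))
  tab <- component_group_ttest(A, groups)
  expect_equal(tab$df, rep(61, 3))          # 28 + 35 - 2
  expect_true(all(tab$p >= 0 & tab$p <= 1))

  # identical loading values in both groups: t = 0, p = 1
  tab0 <- component_group_ttest(cbind(rep(5, 63)), groups)
  expect_equal(tab0$t, 0)
  expect_equal(tab0$p, 1)
})

test_that("a strong mean shift is detected essentially always", {
  set.seed(62)
  rejections <- vapply(1:500, function(i) {
    x <- c(rnorm(28), rnorm(35, mean = 1.5))
    component_group_ttest(cbind(x), rep(c("HC", "SZ"), c(28, 35)))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.99)
})

test_that("t-test p agrees with a permutation oracle", {
  set.seed(63)
  x <- c(rnorm(12), rnorm(14, mean = 0.8))
  g <- rep(c("a", "b"), c(12, 14))
  p_param <- component_group_ttest(cbind(x), g)$p
  obs <- abs(mean(x[g == "a"]) - mean(x[g == "b"]))
  perm <- vapply(1:10000, function(i) {
    gp <- sample(g)
    abs(mean(x[gp == "a"]) - mean(x[gp == "b"])) >= obs - 1e-12
  }, logical(1))
  p_perm <- mean(perm)
  expect_lt(abs(p_param - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
})

test_that("component labels follow the common/unique definition", {
  p <- rbind(mod1 = c(0.01, 0.01, 0.2),
             mod2 = c(0.20, 0.20, 0.3),
             mod3 = c(0.03, 0.20, 0.4))
  lab <- label_components(p)
  expect_equal(lab$label, c("modality-common", "modality-unique", "none"))
  expect_equal(lab$modalities[1], "mod1,mod3")
  expect_equal(lab$modalities[2], "mod1")
  # invariant to modality ordering
  lab2 <- label_components(p[c(3, 1, 2), ])
  expect_equal(lab2$label, lab$label)
})

test_that("loading correlations reproduce the r-to-p transform", {
  # r = 0.38 at N = 63 -> p ~ 0.002 ; r = 0.28 -> p ~ 0.025
  set.seed(64)
  make_pair <- function(r, n = 63) {
    x <- scale(rnorm(n))
    y <- scale(r * x + sqrt(1 - r^2) * scale(rnorm(n)))
    # orthogonalize to hit r exactly
    e <- scale(resid(lm(rnorm(n) ~ x)))
    y <- r * x + sqrt(1 - r^2) * e
    cbind(x = as.numeric(x), y = as.numeric(y))
  }
  p1 <- make_pair(0.38)
  tab1 <- intermodality_loading_correlation(cbind(p1[, 1]), cbind(p1[, 2]))
  expect_equal(tab1$r, 0.38, tolerance = 1e-8)
  expect_lt(abs(tab1$p - 0.002), 0.001)
  p2 <- make_pair(0.28)
  tab2 <- intermodality_loading_correlation(cbind(p2[, 1]), cbind(p2[, 2]))
  expect_lt(abs(tab2$p - 0.025), 0.005)
  # identical columns: r = 1, p = 0
  x <- rnorm(20)
  tab3 <- intermodality_loading_correlation(cbind(x), cbind(x))
  expect_equal(tab3$r, 1)
  expect_lt(tab3$p, 1e-300)
  expect_error(intermodality_loading_correlation(cbind(rep(1, 20)), cbind(x)),
               "zero-variance")
})

test_that("correlation p agrees with a permutation oracle", {
  set.seed(65)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  p_param <- intermodality_loading_correlation(cbind(x), cbind(y))$p
  obs <- abs(cor(x, y))
  p_perm <- mean(vapply(1:10000, function(i) {
    abs(cor(x, sample(y))) >= obs - 1e-12
  }, logical(1)))
  expect_lt(abs(p_param - p_perm),
            3 * sqrt(max(p_perm, 1e-4) * (1 - p_perm) / 10000) + 0.01)
})

test_that("clinical correlations behave at the null and the extreme", {
  set.seed(66)
  A <- matrix(rnorm(35 * 2), 35, 2)
  # proportional scores: r = 1
  tab <- clinical_correlation(cbind(A[, 1]), 3 * A[, 1] + 2)
  expect_equal(tab$r, 1, tolerance = 1e-12)
  # type-I error near alpha under the null
  hits <- vapply(1:500, function(i) {
    clinical_correlation(cbind(rnorm(35)), rnorm(35))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02 + 0.02)
  expect_error(clinical_correlation(A, rep(3, 35)), "constant")
  # NA scores dropped pairwise
  s <- rnorm(35); s[1:5] <- NA
  expect_equal(clinical_correlation(A, s)$n_used, c(30, 30))
})

test_that("Z maps scale by the voxel sd and threshold strictly", {
  row <- c(4, -3.6, 1, 0.5) * 2
  z <- component_zmap(row)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z, row / sd(row))
  set.seed(67)
  z2 <- component_zmap(rnorm(5000, sd = 3))
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  # idempotent up to scale
  expect_equal(component_zmap(z2), z2, tolerance = 1e-12)
  expect_error(component_zmap(rep(2, 10)), "zero-sd")

  expect_equal(threshold_mask(c(4, -3.6, 1, 0), 3.5), c(1L, 2L))
  expect_equal(threshold_mask(c(3.5, -3.5), 3.5), integer(0))  # strict
  expect_length(threshold_mask(c(2.6, -2.7, 0.1), 2.5), 2)
  expect_error(threshold_mask(c(1, 2), 0), "positive")
})

test_that("null cohorts flag about alpha of components per modality", {
  set.seed(68)
  frac <- replicate(60, {
    A <- matrix(rnorm(40 * 5), 40, 5)
    mean(component_group_ttest(A, rep(c("a", "b"), each = 20))$significant)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.025)
})

test_that("stats tables stack modalities and support BH adjustment", {
  g <- small_study(seed = 9, N = 40, L = c(400, 500), M = 3,
                   rho = c(0.6, 0.3, 0), d = c(1.5, 0, 0))
  fr <- suppressWarnings(fuse(g$mats, fusion_config(M = 3, seed = 9)))
  tab <- component_stats_table(fr, g$truth$groups, adjust = TRUE)
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(c("modality", "t", "p", "q") %in% names(tab)))
  expect_true(all(tab$q >= tab$p - 1e-12))
})
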