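test_that("the generator is deterministic and super-Gaussian", {
  g1 <- small_study(seed = 12)
  g2 <- small_study(seed = 12)
  expect_identical(lapply(g1$mats, `[[`, "data"),
                   lapply(g2$mats, `[[`, "data"))
  expect_identical(g1$truth$S_true, g2$truth$S_true)
  for (S in g1$truth$S_true) {
    kurt <- apply(S, 1, nwayfusion:::excess_kurtosis)
    expect_true(all(kurt > 0))
    # rows centered, unit variance
    expect_lt(max(abs(rowMeans(S))), 1e-10)
    expect_equal(apply(S, 1, sd), rep(1, nrow(S)), tolerance = 1e-8)
    # mutually near-uncorrelated within modality
    cc <- cor(t(S))
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.1 + 1e-8)
  }
})

test_that("realized mixing correlations track the target profile", {
  # rho = 0 everywhere: all empirical cross-modality correlations small
  ok0 <- vapply(1:20, function(s) {
    g <- generate_multimodal(N = 200, L_list = c(300, 300), M = 3,
                             rho = rep(0, 3), noise_sd = 0.2, seed = s)
    all(abs(g$truth$realized_rho) < 0.15)
  }, logical(1))
  expect_gte(mean(ok0), 0.9)

  # rho(1) = 0.8 lands within +-0.1 at N = 200
  ok8 <- vapply(1:20, function(s) {
    g <- generate_multimodal(N = 200, L_list = c(300, 300), M = 3,
                             rho = c(0.8, 0.4, 0), noise_sd = 0.2,
                             seed = 100 + s)
    abs(g$truth$realized_rho[1, 1] - 0.8) <= 0.1
  }, logical(1))
  expect_gte(mean(ok8), 0.9)
})

test_that("realized rho converges to the target as N grows", {
  err <- vapply(c(50, 200, 1000), function(N) {
    e <- vapply(1:10, function(s) {
      g <- generate_multimodal(N = N, L_list = c(200, 200), M = 2,
                               rho = c(0.6, 0.3), noise_sd = 0.2,
                               seed = 40 + s)
      mean(abs(g$truth$realized_rho - c(0.6, 0.3)))
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(err[3] < err[1])
})

test_that("group shifts move the designated mixing columns", {
  g <- generate_multimodal(N = 100, L_list = c(300, 300), M = 3,
                           rho = c(0.5, 0.3, 0), d = c(1.5, 0, 0),
                           n_group1 = 50, noise_sd = 0.1, seed = 13)
  for (A in g$truth$A_true) {
    delta1 <- mean(A[1:50, 1]) - mean(A[51:100, 1])
    expect_gt(delta1, 0.5)
    expect_lt(abs(mean(A[1:50, 2]) - mean(A[51:100, 2])), 0.6)
  }
  expect_error(generate_multimodal(N = 20, L_list = c(300, 300), M = 2,
                                   rho = c(1, 0), seed = 1),
               "rho")
  expect_error(generate_multimodal(N = 3, L_list = c(300, 300), M = 2,
                                   seed = 1, rho = c(0, 0)),
               "N >= 2 M")
})

test_that("optimal matching recovers permutations and beats noise", {
  set.seed(14)
  S <- laplace_sources(5, 2000)
  perm <- c(4, 1, 5, 2, 3)
  flip <- c(1, -1, 1, -1, 1)
  S_est <- (S * flip)[perm, ]   # est row i = signed true row perm[i]
  m <- match_components(S_est, S)
  expect_equal(m$permutation, order(perm))
  expect_equal(m$scores, rep(1, 5), tolerance = 1e-10)
  # permutation + signs reconstruct the truth exactly
  recon <- S_est[m$permutation, ] * m$signs
  expect_lt(max(abs(recon - S)), 1e-10)

  # noisy estimates still match well
  S_noisy <- S + matrix(rnorm(5 * 2000, sd = sqrt(1 / 10)), 5, 2000)
  expect_gt(mean(match_components(S_noisy, S)$scores), 0.95)

  # random orthogonal rows match poorly
  Q <- qr.Q(qr(matrix(rnorm(2000 * 5), 2000, 5)))
  expect_lt(mean(match_components(t(Q), S)$scores), 0.2)
})

test_that("the assignment solver is optimal (brute-force oracle)", {
  for (s in 1:25) {
    set.seed(200 + s)
    n <- sample(2:6, 1)
    gain <- matrix(runif(n * n), n, n)
    p_hung <- nwayfusion:::.hungarian_min(-gain)
    oracle <- brute_force_assignment(gain)
    expect_equal(sum(gain[cbind(seq_len(n), p_hung)]), oracle$value,
                 tolerance = 1e-12)
  }
})

test_that("recovery_report scores the perfect result as perfect", {
  g <- small_study(seed = 15, N = 40, L = c(300, 350), M = 3,
                   rho = c(0.6, 0.3, 0), d = rep(0, 3))
  perfect <- structure(list(S = g$truth$S_true, A = g$truth$A_true,
                            M = 3L, modalities = g$truth$modalities),
                       class = "fusion_result")
  rr <- recovery_report(perfect, g$truth)
  expect_equal(rr$summary$mean_source_recovery, rep(1, 2), tolerance = 1e-10)
  expect_equal(rr$summary$mean_mixing_recovery, rep(1, 2), tolerance = 1e-10)
  expect_equal(rr$summary$amari, rep(0, 2), tolerance = 1e-8)

  truncated <- perfect
  truncated$S <- lapply(truncated$S, function(s) s[, -1])
  expect_error(recovery_report(truncated, g$truth), "mismatch")
})
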