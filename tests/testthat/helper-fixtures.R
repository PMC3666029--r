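# Fixture builders shared across the test files.

# Super-Gaussian (Laplace) source matrix, rows unit variance.
laplace_sources <- function(M, L) {
  s <- matrix(stats::rexp(M * L) * sign(stats::runif(M * L) - 0.5), M, L)
  s / apply(s, 1, stats::sd)
}

# Two (or n) reduced datasets linked through shared latent factors, for
# CCA-equivalence checks. Returns centered N x M matrices.
linked_gaussian_sets <- function(N, M, n_sets = 2, strength = 1) {
  z <- matrix(stats::rnorm(N * M), N, M)
  lapply(seq_len(n_sets), function(k) {
    y <- strength * z %*% matrix(stats::rnorm(M * M), M, M) +
      matrix(stats::rnorm(N * M), N, M)
    sweep(y, 2, colMeans(y))
  })
}

# Classical two-set CCA canonical correlations via the generalized
# eigenproblem on covariance blocks (independent closed-form oracle).
cca_oracle <- function(Y1, Y2) {
  Y1 <- sweep(Y1, 2, colMeans(Y1)); Y2 <- sweep(Y2, 2, colMeans(Y2))
  n <- nrow(Y1)
  S11 <- crossprod(Y1) / (n - 1); S22 <- crossprod(Y2) / (n - 1)
  S12 <- crossprod(Y1, Y2) / (n - 1)
  Mmat <- solve(S11, S12) %*% solve(S22, t(S12))
  sqrt(pmax(Re(eigen(Mmat, only.values = TRUE)$values), 0))
}

# Tiny synthetic study: sources + correlated mixing + group shift, small
# enough for fast end-to-end tests.
small_study <- function(seed = 1, N = 60, L = c(600, 700, 800), M = 4,
                        rho = c(0.7, 0.5, 0.3, 0), d = c(1.2, 0, 0, 0),
                        noise_sd = 0.2) {
  generate_multimodal(N = N, L_list = L, M = M, rho = rho, d = d,
                      noise_sd = noise_sd, seed = seed)
}

# Brute-force optimal assignment oracle (maximizing total gain).
brute_force_assignment <- function(gain) {
  n <- nrow(gain)
  perms <- .permutations(n)
  best <- -Inf; best_p <- NULL
  for (i in seq_len(nrow(perms))) {
    v <- sum(gain[cbind(seq_len(n), perms[i, ])])
    if (v > best) { best <- v; best_p <- perms[i, ] }
  }
  list(perm = best_p, value = best)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Write a numeric array as a NIfTI volume and return the path.
write_test_volume <- function(arr, path = tempfile(fileext = ".nii.gz")) {
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  path
}
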