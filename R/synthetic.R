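#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Emulates the generative model the fusion method assumes: per modality
#' `k`, `X_k = A_k S_k + noise`. Sources are sparse Gaussian blobs on a
#' virtual 3-D grid (random centers, radius 2-5 grid units), centered and
#' scaled to unit variance — spatially sparse, hence super-Gaussian, which
#' is what the logistic Infomax stage expects of component maps. The
#' mixing columns of matching index share a latent subject factor,
#'
#'   A_k[, m] = sqrt(rho_m) z_m + sqrt(1 - rho_m) eps_{k,m},
#'
#' so their expected cross-modality correlation is `rho[m]`. Group effects
#' are additive mean shifts: the first `n_group1` rows of a designated
#' mixing column are shifted by `d[m]` times the column's sd. Sources
#' within a modality are regenerated (bounded retries) until mutually
#' near-uncorrelated (|r| < 0.1).
#'
#' @param N number of subjects.
#' @param L_list integer vector of per-modality voxel counts (each at least
#'   `10 * M`).
#' @param M number of components.
#' @param rho length-M correlation profile, entries in \[0, 1).
#' @param d length-M group effect sizes (sd units on the mixing columns);
#'   default all zero.
#' @param noise_sd additive Gaussian noise sd per modality (scalar or
#'   length-n vector).
#' @param n_group1 size of group 1 (its subjects occupy the first rows).
#' @param seed integer seed; the output is bit-identical given it.
#' @param modalities optional modality names.
#'
#' @return A list with `mats` (list of [feature_matrix()]) and `truth`
#'   (class `synthetic_truth`: `S_true`, `A_true`, `rho`, `realized_rho`,
#'   `d`, `noise_sd`, `groups`, `seed`).
#' @export
generate_multimodal <- function(N, L_list, M, rho = rep(0, M),
                                d = rep(0, M), noise_sd = 0.2,
                                n_group1 = floor(N / 2), seed = 1L,
                                modalities = NULL) {
  n_mod <- length(L_list)
  if (N < 2 * M) stop_precondition("need N >= 2 M subjects")
  if (any(L_list < 10 * M)) stop_precondition("each L_k must be >= 10 M")
  if (length(rho) != M) stop_precondition("rho must have length M")
  if (any(rho < 0 | rho >= 1)) {
    stop_precondition("rho entries must lie in [0, 1)")
  }
  if (length(d) != M) stop_precondition("d must have length M")
  if (n_group1 >= N || n_group1 < 1) stop_precondition("invalid n_group1")
  noise_sd <- rep_len(noise_sd, n_mod)
  if (is.null(modalities)) modalities <- sprintf("mod%d", seq_len(n_mod))

  with_seed(seed, {
    S_true <- lapply(seq_len(n_mod), function(k) {
      .blob_sources(M, L_list[k])
    })
    # redraw the mixing until the realized cross-modality correlations sit
    # within 0.1 of the target profile (enforceable for N >= 100; smaller
    # cohorts keep the first draw)
    A_true <- NULL
    for (attempt in 1:50) {
      z <- matrix(stats::rnorm(N * M), N, M)    # shared latent factors
      cand <- lapply(seq_len(n_mod), function(k) {
        eps <- matrix(stats::rnorm(N * M), N, M)
        sweep(z, 2, sqrt(rho), "*") + sweep(eps, 2, sqrt(1 - rho), "*")
      })
      dev <- max(vapply(utils::combn(n_mod, 2, simplify = FALSE),
                        function(pr) {
                          max(abs(matched_col_cor(cand[[pr[1]]],
                                                  cand[[pr[2]]]) - rho))
                        }, numeric(1)))
      if (is.null(A_true)) A_true <- cand
      if (dev < 0.1) { A_true <- cand; break }
      if (N < 100) break
    }
    A_true <- lapply(A_true, function(a) {
      for (m in seq_len(M)) {
        if (d[m] != 0) {
          a[seq_len(n_group1), m] <- a[seq_len(n_group1), m] +
            d[m] * stats::sd(a[, m])
        }
      }
      a
    })
    mats <- lapply(seq_len(n_mod), function(k) {
      x <- A_true[[k]] %*% S_true[[k]] +
        matrix(stats::rnorm(N * L_list[k], sd = noise_sd[k]), N, L_list[k])
      dims <- .virtual_grid(L_list[k])
      feature_matrix(x, modalities[k],
                     mask_coords = arrayInd(seq_len(L_list[k]), dims),
                     grid_shape = dims)
    })
    realized <- matrix(NA_real_, choose(n_mod, 2), M)
    pairs <- utils::combn(n_mod, 2)
    for (p in seq_len(ncol(pairs))) {
      realized[p, ] <- matched_col_cor(A_true[[pairs[1, p]]],
                                       A_true[[pairs[2, p]]])
    }
    truth <- structure(list(S_true = S_true, A_true = A_true,
                            rho = rho, realized_rho = realized,
                            d = d, noise_sd = noise_sd,
                            groups = factor(rep(c("g1", "g2"),
                                                c(n_group1, N - n_group1))),
                            modalities = modalities,
                            seed = as.integer(seed)),
                       class = "synthetic_truth")
    list(mats = mats, truth = truth)
  })
}

# Virtual grid for L voxels: a 2-D sheet (depth 1) large enough that
# radius-2..5 blobs stay sparse (a handful of blobs covers ~5-20% of it).
.virtual_grid <- function(L) {
  side <- ceiling(sqrt(L))
  c(side, ceiling(L / side), 1L)
}

# M sparse blob sources on the virtual grid covering L voxels; rows are
# centered, unit variance, mutually near-uncorrelated (best of bounded
# retries).
.blob_sources <- function(M, L, max_retry = 400L) {
  dims <- .virtual_grid(L)
  coords <- arrayInd(seq_len(L), dims)
  S <- matrix(0, M, L)
  for (m in seq_len(M)) {
    best <- NULL; best_r <- Inf
    for (attempt in seq_len(max_retry)) {
      cand <- .one_blob_source(coords, dims)
      if (excess_kurtosis(cand) < 0.5) next   # must be super-Gaussian
      if (m == 1) { best <- cand; break }
      rmax <- max(abs(stats::cor(cand, t(S[seq_len(m - 1), , drop = FALSE]))))
      if (rmax < best_r) { best <- cand; best_r <- rmax }
      if (rmax < 0.1) break
    }
    if (is.null(best)) best <- .one_blob_source(coords, dims)
    if (m > 1 && best_r >= 0.1) {
      # residualize against earlier sources: removes the (small) shared
      # part while leaving the blob structure essentially intact
      prev <- t(S[seq_len(m - 1), , drop = FALSE])
      best <- best - drop(prev %*% solve(crossprod(prev),
                                         crossprod(prev, best)))
      best <- best - mean(best)
      best <- best / stats::sd(best)
    }
    S[m, ] <- best
  }
  S
}

.one_blob_source <- function(coords, dims) {
  # few blobs on a small field, more on a large one, so coverage stays low
  n_max <- max(2, min(6, floor(nrow(coords) / 300)))
  n_blob <- if (n_max > 2) sample(2:n_max, 1) else 2L
  v <- numeric(nrow(coords))
  for (b in seq_len(n_blob)) {
    center <- vapply(dims, function(dd) stats::runif(1, 1, dd), numeric(1))
    radius <- stats::runif(1, 2, 5)
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
    d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
      (coords[, 3] - center[3])^2
    v <- v + amp * exp(-d2 / (2 * radius^2))
  }
  v <- v - mean(v)
  s <- stats::sd(v)
  if (s < 1e-12) v else v / s
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: %d modalities, M = %d, seed %d>\n",
              length(x$S_true), length(x$rho), x$seed))
  invisible(x)
}

# Hungarian algorithm (O(n^3), potentials formulation); minimizes total
# cost; returns p with p[i] = column assigned to row i.
.hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)   # col 1 is the dummy column
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (jj in 2:(n + 1)) {
        if (!used[jj]) {
          cur <- cost[i0, jj - 1] - u[i0] - v[jj]
          if (cur < minv[jj]) { minv[jj] <- cur; way[jj] <- j0 }
          if (minv[jj] < delta) { delta <- minv[jj]; j1 <- jj }
        }
      }
      for (jj in seq_len(n + 1)) {
        if (used[jj]) {
          if (p[jj] > 0) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        } else {
          minv[jj] <- minv[jj] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (jj in 2:(n + 1)) if (p[jj] > 0) ans[p[jj]] <- jj - 1L
  ans
}

#' Match estimated components to ground truth
#'
#' Finds the one-to-one assignment of estimated to true components that
#' maximizes the total absolute row correlation (optimal assignment, not
#' greedy), together with the signs making matched correlations positive.
#' Extra estimated components stay unmatched; when there are fewer
#' estimated than true components the unmatched true components score 0
#' (and get `NA` in the permutation). Zero-variance rows are excluded with
#' a warning.
#'
#' @param S_est estimated source matrix (rows = components).
#' @param S_true true source matrix with the same number of columns.
#' @return A list: `permutation` (index into rows of `S_est` for each true
#'   component, NA when unmatched), `signs`, `scores` (matched |r| per
#'   true component, 0 when unmatched).
#' @export
match_components <- function(S_est, S_true) {
  S_est <- as.matrix(S_est); S_true <- as.matrix(S_true)
  if (ncol(S_est) != ncol(S_true)) stop_dim("voxel counts differ")
  ok_est <- apply(S_est, 1, stats::sd) > 1e-12
  ok_true <- apply(S_true, 1, stats::sd) > 1e-12
  if (!all(ok_est) || !all(ok_true)) {
    warning("zero-variance component row(s) excluded from matching")
  }
  Mt <- nrow(S_true); Me <- nrow(S_est)
  cmat <- matrix(0, Mt, Me)
  cmat[ok_true, ok_est] <- stats::cor(t(S_true[ok_true, , drop = FALSE]),
                                      t(S_est[ok_est, , drop = FALSE]))
  n <- max(Mt, Me)
  cost <- matrix(0, n, n)   # pad the short side with zero-gain dummies
  cost[seq_len(Mt), seq_len(Me)] <- -abs(cmat)
  assign <- .hungarian_min(cost)[seq_len(Mt)]
  matched <- assign <= Me
  scores <- numeric(Mt); signs <- rep(1, Mt)
  scores[matched] <- abs(cmat[cbind(which(matched), assign[matched])])
  sg <- sign(cmat[cbind(which(matched), assign[matched])])
  sg[sg == 0] <- 1
  signs[matched] <- sg
  assign[!matched] <- NA_integer_
  list(permutation = assign, signs = signs, scores = scores)
}

#' Score a fusion result against synthetic ground truth
#'
#' Matches the estimated sources to the true ones within each modality
#' (components whose mixing correlation across modalities is near zero
#' have no identifiable cross-modality pairing, so matching is per
#' modality), then scores per-component source recovery (matched |r|),
#' mixing recovery (|r| between matched loading columns), and a
#' per-modality Amari index between `pinv(A_est)` and `A_true`.
#'
#' @param result a `fusion_result` from [fuse()] (its M must be at least
#'   the true M).
#' @param truth a `synthetic_truth` from [generate_multimodal()].
#' @return A list of class `recovery_report`: `per_component` (data.frame:
#'   modality, component, source_r, mixing_r), `summary` (per modality:
#'   mean_source_recovery, mean_mixing_recovery, amari), `matching`.
#' @export
recovery_report <- function(result, truth) {
  n_mod <- length(truth$S_true)
  if (length(result$S) != n_mod) {
    stop_dim("modality counts of result and truth differ")
  }
  Mt <- nrow(truth$S_true[[1]])
  for (k in seq_len(n_mod)) {
    if (ncol(result$S[[k]]) != ncol(truth$S_true[[k]])) {
      stop_dim(sprintf("voxel count mismatch in modality %d", k))
    }
  }
  per <- list(); summ <- list(); mt <- list()
  for (k in seq_len(n_mod)) {
    mt[[k]] <- match_components(result$S[[k]], truth$S_true[[k]])
    perm <- mt[[k]]$permutation
    src_r <- mt[[k]]$scores
    mix_r <- vapply(seq_len(Mt), function(m) {
      if (is.na(perm[m])) return(0)
      abs(stats::cor(result$A[[k]][, perm[m]], truth$A_true[[k]][, m]))
    }, numeric(1))
    per[[k]] <- data.frame(modality = truth$modalities[k],
                           component = seq_len(Mt),
                           source_r = src_r, mixing_r = mix_r)
    amari <- if (result$M == Mt) {
      Aest <- result$A[[k]]
      amari_index(solve(crossprod(Aest), t(Aest)) %*% truth$A_true[[k]],
                  diag(Mt))
    } else NA_real_
    summ[[k]] <- data.frame(modality = truth$modalities[k],
                            mean_source_recovery = mean(src_r),
                            mean_mixing_recovery = mean(mix_r),
                            amari = amari)
  }
  structure(list(per_component = do.call(rbind, per),
                 summary = do.call(rbind, summ),
                 matching = mt),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary, digits = 3)
  invisible(x)
}
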