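#' Multiset canonical correlation analysis (SSQCOR)
#'
#' Finds, for each of `n >= 2` reduced modalities, a linear transform
#' `w_k` such that the canonical variates `D_k = Y_k w_k` maximize the sum
#' of squared cross-modality correlations between matching columns, under
#' the constraints `D_k' D_k / (N - 1) = I` (unit variance, mutually
#' uncorrelated variates within each modality).
#'
#' The optimization is stage-wise (deflationary): for component `m`, each
#' `w_k` is updated in turn with the others held fixed, which reduces to
#' the dominant eigenvector of a generalized eigenproblem and can only
#' increase the objective; stages after the first operate on data with the
#' earlier variates projected out, so the constraints hold by construction.
#' Initialization is the deterministic MAXVAR eigenvector of the stacked
#' correlation matrix, so the fit needs no seed.
#'
#' @param Y_list list of `reduced_data` objects (or plain N x M matrices
#'   with centered columns), all sharing the subject dimension N.
#' @param M number of canonical components; defaults to the smallest
#'   modality width.
#' @param tol relative objective change declaring stage convergence
#'   (default 1e-10).
#' @param max_iter maximum update cycles per stage (default 1000).
#' @param ridge relative ridge added to each within-modality covariance
#'   for numerical stability (default 1e-8).
#'
#' @return A list of class `canonical_set` with fields `D` (list of N x M
#'   variate matrices), `w` (list of M x M transforms, `D_k = Y_k w_k`),
#'   `r_profile` (data.frame: component, pair, r), `mean_sq_cor` (per
#'   component, used for sorting), `objective_trace` (cumulative SSQCOR
#'   objective per update cycle), and `converged`.
#' @export
fit_mcca <- function(Y_list, M = NULL, tol = 1e-10, max_iter = 1000,
                     ridge = 1e-8) {
  ys <- lapply(Y_list, function(y) {
    if (inherits(y, "reduced_data")) y$Y else as.matrix(y)
  })
  n_mod <- length(ys)
  if (n_mod < 2) stop_precondition("multiset CCA needs at least 2 modalities")
  N <- nrow(ys[[1]])
  if (any(vapply(ys, nrow, 1L) != N)) {
    stop_dim("all modalities must share the subject dimension")
  }
  widths <- vapply(ys, ncol, 1L)
  if (is.null(M)) M <- min(widths)
  if (M > min(widths)) stop_precondition("M exceeds a modality width")
  if (N <= M) stop_precondition("need more subjects than components")

  # center defensively (reduced data is already column-centered)
  ys <- lapply(ys, function(y) sweep(y, 2, colMeans(y)))

  D <- lapply(widths, function(w) matrix(0, N, M))
  Wmats <- lapply(widths, function(w) matrix(0, w, M))
  # deflation transforms: deflated data = Y_k %*% Tk[[k]]
  Tk <- lapply(widths, function(w) diag(w))
  trace <- numeric(0)
  converged <- TRUE
  done_obj <- 0

  for (m in seq_len(M)) {
    Yd <- lapply(seq_len(n_mod), function(k) ys[[k]] %*% Tk[[k]])
    # covariance blocks of the deflated data
    S <- vector("list", n_mod)
    for (k in seq_len(n_mod)) {
      S[[k]] <- lapply(seq_len(n_mod), function(j) {
        crossprod(Yd[[k]], Yd[[j]]) / (N - 1)
      })
    }
    Skk_r <- lapply(seq_len(n_mod), function(k) {
      s <- S[[k]][[k]]
      s + diag(ridge * sum(diag(s)) / ncol(s), ncol(s))
    })

    w <- .mcca_init(Yd, S, Skk_r)
    obj_old <- .ssqcor_objective(S, w)
    trace <- c(trace, done_obj + obj_old)
    it <- 0
    repeat {
      it <- it + 1
      for (k in seq_len(n_mod)) {
        # maximize sum_j (w_k' S_kj w_j)^2  s.t.  w_k' S_kk w_k = 1
        Mk <- matrix(0, widths[k], widths[k])
        for (j in seq_len(n_mod)) {
          if (j == k) next
          v <- S[[k]][[j]] %*% w[[j]]
          Mk <- Mk + tcrossprod(v)
        }
        w[[k]] <- .top_gen_eigvec(Mk, Skk_r[[k]], S[[k]][[k]])
      }
      obj <- .ssqcor_objective(S, w)
      trace <- c(trace, done_obj + obj)
      if (obj - obj_old <= tol * max(obj, 1) || it >= max_iter) {
        if (it >= max_iter && obj - obj_old > tol * max(obj, 1)) {
          converged <- FALSE
        }
        break
      }
      obj_old <- obj
    }
    done_obj <- done_obj + obj

    for (k in seq_len(n_mod)) {
      wk_full <- Tk[[k]] %*% w[[k]]
      # exact unit variance against the *original* data
      d <- ys[[k]] %*% wk_full
      sc <- sqrt(sum(d^2) / (N - 1))
      wk_full <- wk_full / sc
      d <- d / sc
      # sign convention: first entry of w with |.| > 1e-12 positive
      nz <- which(abs(wk_full) > 1e-12)
      if (length(nz) && wk_full[nz[1]] < 0) {
        wk_full <- -wk_full; d <- -d
      }
      Wmats[[k]][, m] <- wk_full
      D[[k]][, m] <- d
      # deflate: remove the new variate from modality k's (already
      # deflated) column space; d' (Y T) / (N-1) is the projection row
      Tk[[k]] <- Tk[[k]] -
        wk_full %*% (crossprod(d, ys[[k]] %*% Tk[[k]]) / (N - 1))
    }
  }

  res <- .canonical_set(D, Wmats, N, trace, converged,
                        modalities = vapply(Y_list, function(y) {
                          if (inherits(y, "reduced_data")) y$modality else ""
                        }, character(1)))
  res
}

# package D/w into a sorted canonical_set
.canonical_set <- function(D, Wmats, N, trace, converged, modalities) {
  n_mod <- length(D)
  M <- ncol(D[[1]])
  pairs <- utils::combn(n_mod, 2)
  rows <- list()
  mean_sq <- numeric(M)
  for (m in seq_len(M)) {
    rs <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      k <- pairs[1, p]; j <- pairs[2, p]
      rs[p] <- stats::cor(D[[k]][, m], D[[j]][, m])
    }
    mean_sq[m] <- mean(rs^2)
    rows[[m]] <- data.frame(component = m,
                            pair = sprintf("%d-%d", pairs[1, ], pairs[2, ]),
                            r = rs)
  }
  ord <- order(mean_sq, decreasing = TRUE)
  D <- lapply(D, function(d) d[, ord, drop = FALSE])
  Wmats <- lapply(Wmats, function(w) w[, ord, drop = FALSE])
  prof <- do.call(rbind, rows[ord])
  prof$component <- rep(seq_len(M), each = ncol(pairs))
  structure(list(D = D, w = Wmats, r_profile = prof,
                 mean_sq_cor = mean_sq[ord],
                 objective_trace = trace, converged = converged,
                 modalities = modalities),
            class = "canonical_set")
}

#' @export
print.canonical_set <- function(x, ...) {
  cat(sprintf("<canonical_set: %d modalities, %d components%s>\n",
              length(x$D), ncol(x$D[[1]]),
              if (x$converged) "" else " (NOT converged)"))
  cat("mean squared cross-correlation per component:\n")
  print(round(x$mean_sq_cor, 3))
  invisible(x)
}

# MAXVAR initialization: top eigenvector of the stacked correlation matrix,
# split by modality and normalized to unit variance.
.mcca_init <- function(Yd, S, Skk_r) {
  n_mod <- length(Yd)
  sds <- lapply(Yd, function(y) {
    s <- apply(y, 2, stats::sd)
    s[s < 1e-12] <- 1
    s
  })
  blocks <- vector("list", n_mod)
  for (k in seq_len(n_mod)) {
    blocks[[k]] <- lapply(seq_len(n_mod), function(j) {
      S[[k]][[j]] / outer(sds[[k]], sds[[j]])
    })
  }
  R <- do.call(rbind, lapply(blocks, function(b) do.call(cbind, b)))
  alpha <- eigen(R, symmetric = TRUE)$vectors[, 1]
  idx <- cumsum(vapply(Yd, ncol, 1L))
  starts <- c(1, utils::head(idx, -1) + 1)
  w <- vector("list", n_mod)
  for (k in seq_len(n_mod)) {
    a <- alpha[starts[k]:idx[k]]
    if (sqrt(sum(a^2)) < 1e-10) {
      a <- eigen(Skk_r[[k]], symmetric = TRUE)$vectors[, 1]
    }
    q <- drop(crossprod(a, S[[k]][[k]] %*% a))
    w[[k]] <- if (q > 1e-20) a / sqrt(q) else a
  }
  w
}

.ssqcor_objective <- function(S, w) {
  n_mod <- length(w)
  obj <- 0
  for (k in seq_len(n_mod - 1)) {
    for (j in (k + 1):n_mod) {
      obj <- obj + drop(crossprod(w[[k]], S[[k]][[j]] %*% w[[j]]))^2
    }
  }
  obj
}

# dominant eigenvector of M w = lambda B_r w, rescaled so w' B w = 1
# (B the unridged covariance, B_r its ridged version).
.top_gen_eigvec <- function(M, B_r, B) {
  ch <- tryCatch(chol(B_r), error = function(e) NULL)
  if (is.null(ch)) {
    e <- eigen(B_r, symmetric = TRUE)
    vals <- pmax(e$values, max(e$values) * 1e-12)
    ch <- diag(sqrt(vals)) %*% t(e$vectors)
  }
  # transform to a standard symmetric problem via B_r = R'R:
  # eigvec of R^{-T} M R^{-1}, then map back with w = R^{-1} v
  Ms <- forwardsolve(t(ch), t(forwardsolve(t(ch), M)))
  v <- eigen((Ms + t(Ms)) / 2, symmetric = TRUE)$vectors[, 1]
  w <- backsolve(ch, v)
  q <- drop(crossprod(w, B %*% w))
  if (q > 1e-20) w / sqrt(q) else w
}

#' Associated maps of canonical variates
#'
#' Solves the least-squares problem `X ~ D C` for the component maps `C`,
#' i.e. `C = pinv(D) X`: the spatial patterns whose mixture by the
#' canonical variates best reconstructs the (centered) data.
#'
#' @param X_centered numeric matrix N x L (voxel means removed) or a
#'   [feature_matrix()] whose data will be column-centered.
#' @param D_k canonical variate matrix N x M, full column rank.
#' @return M x L matrix of associated maps.
#' @export
associated_maps <- function(X_centered, D_k) {
  x <- if (inherits(X_centered, "feature_matrix")) {
    sweep(X_centered$data, 2, colMeans(X_centered$data))
  } else as.matrix(X_centered)
  D_k <- as.matrix(D_k)
  qrD <- qr(D_k)
  if (qrD$rank < ncol(D_k)) {
    dep <- setdiff(seq_len(ncol(D_k)), qrD$pivot[seq_len(qrD$rank)])
    stop_data("rank-deficient canonical variates; collinear component(s): ",
              paste(dep, collapse = ", "))
  }
  qr.coef(qrD, x)
}

#' Write a cross-modality correlation profile to CSV
#'
#' @param cset a `canonical_set` from [fit_mcca()].
#' @param path output CSV path (columns: component, pair, r).
#' @return Invisibly, `path`.
#' @export
write_r_profile <- function(cset, path) {
  utils::write.csv(cset$r_profile, path, row.names = FALSE)
  invisible(path)
}
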