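#' Infomax ICA on concatenated component maps
#'
#' Fits a single unmixing matrix `W` to the horizontally concatenated
#' associated maps so that the rows of `S = W C` are maximally independent.
#' The rows of `C` are first sphered (second-moment whitening, no mean
#' removal so the identity `S = W C` is exact); Infomax with the logistic
#' nonlinearity then learns the remaining rotation by natural-gradient
#' ascent over random mini-batches:
#'
#'   dW = lr * (I + (1 - 2 g(u)) u') W,   g(u) = 1 / (1 + exp(-u))
#'
#' The learning rate is annealed (factor `anneal`) whenever the weights
#' blow up — in which case the last stable weights are restored — or when
#' the epoch-to-epoch update direction swings by more than 60 degrees
#' (the usual sign of oscillation around the optimum). The fit stops when
#' the epoch weight change drops below `tol`.
#'
#' The logistic score separates super-Gaussian (spatially sparse) sources,
#' which is the regime feature maps live in; near-Gaussian rows are
#' reported with a warning since ICA cannot identify them.
#'
#' @param C_concat numeric matrix, M components (rows) by total voxels.
#' @param seed integer seed controlling the initial weights and batch
#'   order; the fit is bit-reproducible given the seed.
#' @param lr0 initial learning rate (default 0.001).
#' @param tol weight-change norm declaring convergence (default 1e-6).
#' @param max_steps maximum training epochs (default 512).
#' @param anneal learning-rate annealing factor (default 0.9).
#'
#' @return A list of class `unmixing_result`: `W` (M x M total unmixing,
#'   sphering folded in), `S_concat = W %*% C_concat`, `converged`,
#'   `n_steps`, `seed`, `nonlinearity` (`"logistic"`), `condition_number`
#'   of `W`, `objective_trace` (full-data Infomax log-likelihood per
#'   epoch), and `near_gaussian` (logical per row of `S_concat`).
#' @export
fit_infomax <- function(C_concat, seed = 1L, lr0 = 0.001, tol = 1e-6,
                        max_steps = 512L, anneal = 0.9) {
  C_concat <- as.matrix(C_concat)
  M <- nrow(C_concat); L <- ncol(C_concat)
  if (M < 2) stop_precondition("Infomax needs at least 2 components")
  if (L <= M) stop_precondition("need more voxels than components")
  rsd <- apply(C_concat, 1, stats::sd)
  if (any(rsd < 1e-12)) {
    stop_data("constant row(s) in the concatenated maps: ",
              paste(which(rsd < 1e-12), collapse = ", "))
  }

  # second-moment sphering (mean not removed: S = W C must hold exactly)
  R <- tcrossprod(C_concat) / L
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-12)
  sph <- e$vectors %*% diag(1 / sqrt(vals)) %*% t(e$vectors)
  Z <- sph %*% C_concat

  batch <- ceiling(L / 64)
  res <- with_seed(seed, {
    W <- diag(M) + matrix(stats::rnorm(M * M, sd = 1e-3), M, M)
    lr <- lr0
    W_good <- W
    dW_old <- NULL
    obj_trace <- numeric(0)
    converged <- FALSE
    step <- 0
    n_anneal <- 0
    while (step < max_steps) {
      step <- step + 1
      W_prev <- W
      perm <- sample.int(L)
      blown <- FALSE
      for (b in seq_len(ceiling(L / batch))) {
        idx <- perm[((b - 1) * batch + 1):min(b * batch, L)]
        u <- W %*% Z[, idx, drop = FALSE]
        g <- 1 / (1 + exp(-u))
        W <- W + (lr / length(idx)) *
          ((diag(M) * length(idx) + (1 - 2 * g) %*% t(u)) %*% W)
        if (any(!is.finite(W)) || max(abs(W)) > 1e8) {
          blown <- TRUE
          break
        }
      }
      if (blown) {
        lr <- lr * anneal
        W <- W_good
        dW_old <- NULL
        n_anneal <- n_anneal + 1
        if (n_anneal > 200) break
        next
      }
      W_good <- W
      dW <- W - W_prev
      change <- sqrt(sum(dW^2))
      obj_trace <- c(obj_trace, .infomax_objective(W, Z))
      if (!is.null(dW_old)) {
        denom <- sqrt(sum(dW^2)) * sqrt(sum(dW_old^2))
        if (denom > 0) {
          cosang <- sum(dW * dW_old) / denom
          if (cosang < cos(60 * pi / 180)) lr <- lr * anneal
        }
      }
      dW_old <- dW
      if (change < tol) {
        converged <- TRUE
        break
      }
    }
    list(W = W, converged = converged, n_steps = step,
         obj_trace = obj_trace, n_anneal = n_anneal)
  })

  W_total <- res$W %*% sph
  S <- W_total %*% C_concat
  kurt <- apply(S, 1, excess_kurtosis)
  near_gaussian <- abs(kurt) < 0.2
  if (any(near_gaussian)) {
    warning(sprintf(
      "%d recovered source(s) are near-Gaussian (|excess kurtosis| < 0.2); ICA cannot identify them",
      sum(near_gaussian)))
  }
  if (!res$converged && res$n_anneal > 200) {
    warning("Infomax diverged despite maximal annealing; result is not converged")
  }
  sv <- svd(W_total, nu = 0, nv = 0)$d
  structure(list(W = W_total, S_concat = S,
                 converged = res$converged, n_steps = res$n_steps,
                 seed = as.integer(seed), nonlinearity = "logistic",
                 condition_number = sv[1] / sv[length(sv)],
                 objective_trace = res$obj_trace,
                 near_gaussian = near_gaussian,
                 source_kurtosis = kurt),
            class = "unmixing_result")
}

# Infomax log-likelihood per sample: log|det W| + mean_t sum_i log g'(u_it)
# with g logistic, log g'(u) = -u - 2 log(1 + exp(-u)).
.infomax_objective <- function(W, Z) {
  u <- W %*% Z
  # numerically stable log(1 + exp(-u))
  lse <- ifelse(u > 0, log1p(exp(-u)), -u + log1p(exp(u)))
  determinant(W, logarithm = TRUE)$modulus[1] +
    sum(-u - 2 * lse) / ncol(Z)
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf(
    "<unmixing_result: %d x %d W, %s in %d steps, cond(W) = %.2g>\n",
    nrow(x$W), ncol(x$W),
    if (x$converged) "converged" else "stopped", x$n_steps,
    x$condition_number))
  invisible(x)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' matrix and a true mixing matrix: 0 if and only if `W_est %*% A` is a
#' scaled permutation (perfect separation up to the inherent ICA
#' ambiguities). Normalized to lie in \[0, 1\].
#'
#' @param W_est estimated unmixing matrix (M x M).
#' @param A true mixing matrix (M x M).
#' @return Non-negative scalar.
#' @export
amari_index <- function(W_est, A) {
  W_est <- as.matrix(W_est); A <- as.matrix(A)
  if (!all(dim(W_est) == dim(A)) || nrow(W_est) != ncol(W_est)) {
    stop_dim("amari_index needs square matrices of equal size")
  }
  P <- abs(W_est %*% A)
  n <- nrow(P)
  if (any(apply(P, 1, max) < 1e-300) || any(apply(P, 2, max) < 1e-300)) {
    stop_data("singular product: Amari index undefined")
  }
  rowterm <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colterm <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (rowterm + colterm) / (2 * n * (n - 1))
}

#' Split concatenated joint sources by modality
#'
#' @param S_concat joint source matrix, M x sum(widths).
#' @param widths integer vector of per-modality voxel counts, in modality
#'   order.
#' @return List of M x `widths[k]` matrices (contiguous column blocks).
#' @export
split_joint_sources <- function(S_concat, widths) {
  S_concat <- as.matrix(S_concat)
  widths <- as.integer(widths)
  if (sum(widths) != ncol(S_concat)) {
    stop_dim(sprintf("widths sum to %d but S_concat has %d columns",
                     sum(widths), ncol(S_concat)))
  }
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(widths), function(k) {
    S_concat[, starts[k]:ends[k], drop = FALSE]
  })
}
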