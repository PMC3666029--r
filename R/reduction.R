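#' Estimate the number of components of one modality by MDL
#'
#' Computes the minimum description length criterion on the eigenvalues of
#' the subject-space covariance `X X' / L` (voxel-mean-centered data) and
#' returns the order minimizing it. For candidate order `m`, with
#' eigenvalues `lambda_1 >= ... >= lambda_p` (p = number of subjects) and
#' `N_eff` effective samples,
#'
#'   MDL(m) = -N_eff * (p - m) * log( geomean(tail) / mean(tail) )
#'            + 0.5 * m * (2p - m) * log(N_eff)
#'
#' where `tail` is the `p - m` smallest eigenvalues. Neighbouring voxels of
#' smoothed brain maps are strongly correlated, so treating every voxel as
#' an independent sample overstates the evidence and inflates the order.
#' With `subsample_correction = TRUE` (default) the effective sample count
#' is reduced to `L / s`, where the stride `s` is the smallest spatial lag
#' at which the voxel autocorrelation (along the stored raster order,
#' pooled over subjects) drops below 0.1.
#'
#' @param X a [feature_matrix()] or plain subjects-by-voxels matrix.
#' @param max_order largest candidate order (must be below the subject
#'   count); default `min(N - 2, 30)`.
#' @param subsample_correction logical; apply the effective-sample
#'   correction (default TRUE).
#'
#' @return A list of class `order_estimate` with `modality`, `order`,
#'   `criterion_curve` (data.frame: order, mdl_value), and
#'   `effective_samples`.
#' @export
estimate_order_mdl <- function(X, max_order = NULL,
                               subsample_correction = TRUE) {
  modality <- if (inherits(X, "feature_matrix")) X$modality else "data"
  x <- if (inherits(X, "feature_matrix")) X$data else as.matrix(X)
  n <- nrow(x); l <- ncol(x)
  if (n < 4) stop_precondition("order estimation needs at least 4 subjects")
  if (is.null(max_order)) max_order <- min(n - 2L, 30L)
  if (max_order >= n) stop_precondition("max_order must be below the subject count")
  xc <- sweep(x, 2, colMeans(x))
  if (max(abs(xc)) == 0) stop_data("constant data: order is undefined")

  ev <- eigen(tcrossprod(xc) / l, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, .Machine$double.eps * max(ev))

  n_eff <- l
  if (subsample_correction) {
    s <- .autocorr_stride(xc)
    n_eff <- max(l / s, n + 1)
  }

  p <- n
  crit <- vapply(seq_len(max_order), function(m) {
    tail_ev <- ev[(m + 1):p]
    ratio <- mean(log(tail_ev)) - log(mean(tail_ev))
    -n_eff * (p - m) * ratio + 0.5 * m * (2 * p - m) * log(n_eff)
  }, numeric(1))
  list(modality = modality,
       order = which.min(crit),
       criterion_curve = data.frame(order = seq_len(max_order),
                                    mdl_value = crit),
       effective_samples = n_eff) |>
    structure(class = "order_estimate")
}

# Smallest lag at which the mean column-order autocorrelation of the rows
# drops below 0.1.
.autocorr_stride <- function(xc, max_lag = 50L, cutoff = 0.1) {
  l <- ncol(xc)
  denom <- sum(xc^2)
  if (denom == 0) return(1L)
  for (h in seq_len(min(max_lag, l - 1L))) {
    r <- sum(xc[, 1:(l - h), drop = FALSE] *
               xc[, (1 + h):l, drop = FALSE]) / denom * l / (l - h)
    if (abs(r) < cutoff) return(h)
  }
  min(max_lag, l - 1L)
}

#' @export
print.order_estimate <- function(x, ...) {
  cat(sprintf("<order_estimate '%s': order %d (N_eff %.0f)>\n",
              x$modality, x$order, x$effective_samples))
  invisible(x)
}

#' Common fusion order across modalities
#'
#' The joint decomposition uses one component count for all modalities; it
#' is taken as the maximum of the per-modality estimates, since a modest
#' overestimate degrades source recovery far less than discarding a true
#' component.
#'
#' @param orders vector (or list) of positive integer per-modality orders.
#' @return The maximum order.
#' @export
choose_fusion_order <- function(orders) {
  orders <- unlist(orders)
  if (length(orders) == 0) stop_precondition("no orders given")
  as.integer(max(orders))
}

#' SVD dimension reduction of one modality
#'
#' Removes voxel-wise means and projects the centered data onto the top-M
#' right singular vectors: `Y = X_c E`, where the columns of `E` are
#' orthonormal and `Y E' + col_means` is the best rank-M approximation of
#' `X` in the Frobenius sense.
#'
#' @param X a [feature_matrix()] or plain subjects-by-voxels matrix.
#' @param M number of dimensions to keep; at most the rank of the centered
#'   data.
#'
#' @return A list of class `reduced_data` with `modality`, `Y` (N x M),
#'   `E` (L x M), `singular_values` (all of them, descending), `col_means`,
#'   and `variance_retained`.
#' @export
reduce_dimensions <- function(X, M) {
  modality <- if (inherits(X, "feature_matrix")) X$modality else "data"
  x <- if (inherits(X, "feature_matrix")) X$data else as.matrix(X)
  n <- nrow(x)
  col_means <- colMeans(x)
  xc <- sweep(x, 2, col_means)
  sv <- svd(xc, nu = min(n, ncol(x)), nv = 0)
  d <- sv$d
  rank <- sum(d > max(d) * 1e-10 * max(dim(x)))
  if (M > rank) {
    stop_precondition(sprintf(
      "M = %d exceeds the achievable rank %d of the centered data", M, rank))
  }
  u <- sv$u[, seq_len(M), drop = FALSE]
  dm <- d[seq_len(M)]
  Y <- u %*% diag(dm, M)
  # E = X_c' u / d  (right singular vectors), computed without the full V
  E <- crossprod(xc, u) %*% diag(1 / dm, M)
  structure(list(modality = modality,
                 Y = Y, E = E,
                 singular_values = d,
                 col_means = col_means,
                 variance_retained = sum(dm^2) / sum(d^2)),
            class = "reduced_data")
}

#' @export
print.reduced_data <- function(x, ...) {
  cat(sprintf("<reduced_data '%s': %d x %d, %.1f%% variance retained>\n",
              x$modality, nrow(x$Y), ncol(x$Y),
              100 * x$variance_retained))
  invisible(x)
}

#' Write an MDL criterion curve to CSV
#'
#' @param est an `order_estimate` from [estimate_order_mdl()].
#' @param path output CSV path (columns: order, mdl_value).
#' @return Invisibly, `path`.
#' @export
write_criterion_curve <- function(est, path) {
  utils::write.csv(est$criterion_curve, path, row.names = FALSE)
  invisible(path)
}
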