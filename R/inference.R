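#' Two-sample t-tests on component loadings
#'
#' Tests, for every component, whether its subject loadings (one column of
#' the mixing matrix `A_k`) differ between the two groups. The default is
#' the classical pooled-variance two-sample t with `n1 + n2 - 2` degrees of
#' freedom and a two-tailed p-value; Welch's unequal-variance form is
#' available via `welch = TRUE`.
#'
#' @param A_k loading matrix, subjects x components.
#' @param groups factor-like vector of length `nrow(A_k)` with exactly two
#'   levels (e.g. `"HC"`, `"SZ"`).
#' @param welch use Welch's t instead of the pooled-variance t.
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#'
#' @return data.frame with one row per component: `component`, `t`, `p`,
#'   `df`, `mean_g1`, `mean_g2`, `sd_g1`, `sd_g2`, `significant`,
#'   `zero_variance_flag`.
#' @export
component_group_ttest <- function(A_k, groups, welch = FALSE, alpha = 0.05) {
  A_k <- as.matrix(A_k)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop_precondition("exactly two groups required")
  g1 <- groups == levels(groups)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop_precondition("each group needs at least 2 subjects")
  out <- lapply(seq_len(ncol(A_k)), function(m) {
    x <- A_k[g1, m]; y <- A_k[g2, m]
    v1 <- stats::var(x); v2 <- stats::var(y)
    zero_var <- (v1 == 0 && n1 == 2) || (v2 == 0 && n2 == 2)
    if (v1 == 0 && v2 == 0) {
      tt <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
      df <- n1 + n2 - 2
      p <- if (tt == 0) 1 else 0
    } else if (welch) {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      tt <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
    } else {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      tt <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
    }
    data.frame(component = m, t = tt, p = p, df = df,
               mean_g1 = mean(x), mean_g2 = mean(y),
               sd_g1 = sqrt(v1), sd_g2 = sqrt(v2),
               significant = p < alpha,
               zero_variance_flag = zero_var)
  })
  do.call(rbind, out)
}

#' Component statistics across all modalities
#'
#' Convenience wrapper: runs [component_group_ttest()] on every modality of
#' a fusion result and stacks the tables, optionally adding
#' Benjamini-Hochberg adjusted q-values.
#'
#' @param result a `fusion_result` from [fuse()].
#' @param groups two-level group labels in subject order.
#' @param alpha significance level (default 0.05).
#' @param adjust add a `q` column with BH-adjusted p-values (computed
#'   within modality); the `significant` flag still uses the raw p, which
#'   is also how results are reported by default.
#' @param welch use Welch's t.
#' @return data.frame with a `modality` column prepended.
#' @export
component_stats_table <- function(result, groups, alpha = 0.05,
                                  adjust = FALSE, welch = FALSE) {
  tabs <- lapply(seq_along(result$A), function(k) {
    tab <- component_group_ttest(result$A[[k]], groups,
                                 welch = welch, alpha = alpha)
    tab <- cbind(modality = result$modalities[k], tab)
    if (adjust) tab$q <- stats::p.adjust(tab$p, method = "BH")
    tab
  })
  do.call(rbind, tabs)
}

#' Label components as modality-common or modality-unique
#'
#' A component index significant (p below `alpha`) in two or more
#' modalities is modality-common (joint); significant in exactly one,
#' modality-unique; otherwise unlabeled.
#'
#' @param p_matrix numeric matrix of p-values, modalities (rows) x
#'   components (columns); row names identify modalities.
#' @param alpha significance level (default 0.05).
#' @return data.frame per component: `component`, `label` (one of
#'   `"modality-common"`, `"modality-unique"`, `"none"`),
#'   `modalities` (comma-separated contributing modalities).
#' @export
label_components <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  if (any(!is.finite(p_matrix))) stop_data("p_matrix must be finite")
  mod_names <- rownames(p_matrix)
  if (is.null(mod_names)) mod_names <- sprintf("mod%d", seq_len(nrow(p_matrix)))
  out <- lapply(seq_len(ncol(p_matrix)), function(m) {
    hits <- which(p_matrix[, m] < alpha)
    label <- if (length(hits) >= 2) "modality-common"
             else if (length(hits) == 1) "modality-unique"
             else "none"
    data.frame(component = m, label = label,
               modalities = paste(sort(mod_names[hits]), collapse = ","))
  })
  do.call(rbind, out)
}

# Pearson r with two-tailed p from t = r sqrt(n-2)/sqrt(1-r^2), n-2 df.
.cor_with_p <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(c(r = r, p = 0))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  c(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Column-wise correlations between two loading matrices
#'
#' Correlates matching columns of two modalities' mixing matrices: a large
#' correlation at a group-discriminative index indicates linked expression
#' of the same joint component across modalities.
#'
#' @param A_i,A_j loading matrices, same subjects and same component count.
#' @return data.frame per component: `component`, `r`, `p` (two-tailed,
#'   from the t transform of r with `N - 2` degrees of freedom).
#' @export
intermodality_loading_correlation <- function(A_i, A_j) {
  A_i <- as.matrix(A_i); A_j <- as.matrix(A_j)
  if (nrow(A_i) != nrow(A_j)) stop_dim("subject counts differ")
  if (ncol(A_i) != ncol(A_j)) stop_dim("component counts differ")
  out <- lapply(seq_len(ncol(A_i)), function(m) {
    if (stats::sd(A_i[, m]) == 0 || stats::sd(A_j[, m]) == 0) {
      stop_data(sprintf("zero-variance loading column for component %d", m))
    }
    rp <- .cor_with_p(A_i[, m], A_j[, m])
    data.frame(component = m, r = unname(rp["r"]), p = unname(rp["p"]))
  })
  do.call(rbind, out)
}

#' Correlation of component loadings with a clinical score
#'
#' Pearson correlation of each loading column against a clinical score
#' (e.g. a PANSS subscale), with a two-tailed p-value. Restricting to a
#' patient subgroup is the caller's job: pass `A_k[groups == "SZ", ]` and
#' the matching scores. Subject pairs with a missing score are dropped.
#'
#' @param A_k loading matrix (already restricted to the cohort of
#'   interest).
#' @param scores numeric vector of length `nrow(A_k)`; NAs are dropped
#'   pairwise.
#' @return data.frame per component: `component`, `r`, `p`, `n_used`.
#' @export
clinical_correlation <- function(A_k, scores) {
  A_k <- as.matrix(A_k)
  keep <- is.finite(scores)
  A_k <- A_k[keep, , drop = FALSE]
  scores <- scores[keep]
  if (length(scores) < 3) {
    stop_precondition("need at least 3 subjects with a score")
  }
  if (stats::sd(scores) == 0) stop_data("constant score vector")
  out <- lapply(seq_len(ncol(A_k)), function(m) {
    if (stats::sd(A_k[, m]) == 0) {
      stop_data(sprintf("zero-variance loading column for component %d", m))
    }
    rp <- .cor_with_p(A_k[, m], scores)
    data.frame(component = m, r = unname(rp["r"]), p = unname(rp["p"]),
               n_used = length(scores))
  })
  do.call(rbind, out)
}

#' Z-scale a component map
#'
#' Divides a source row by its standard deviation across voxels (no mean
#' subtraction: joint sources are near zero-mean by construction), so
#' voxel values are comparable across components and thresholdable on a
#' common |Z| scale.
#'
#' @param S_k_row numeric vector, one component's spatial map.
#' @return Z vector of the same length, sd 1.
#' @export
component_zmap <- function(S_k_row) {
  s <- stats::sd(S_k_row)
  if (!is.finite(s) || s == 0) stop_data("zero-sd component map")
  S_k_row / s
}

#' Threshold a Z map into a voxel index set
#'
#' @param Z numeric vector of Z values.
#' @param tau positive threshold; voxels with `|Z| > tau` (strict) are
#'   kept.
#' @return Integer vector of voxel indices.
#' @export
threshold_mask <- function(Z, tau) {
  if (tau <= 0) stop_precondition("tau must be positive")
  which(abs(Z) > tau)
}
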