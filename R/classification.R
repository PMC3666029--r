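#' Build a masked feature set from discriminative components
#'
#' Selects a modality's group-discriminative components, thresholds each
#' component's Z map at `|Z| > tau`, unions the resulting voxel masks, and
#' restricts the raw (pre-fusion) feature matrix to that union. The raw
#' values in discriminative regions — not the decomposition itself — are
#' what the downstream classifiers see.
#'
#' @param X_k raw feature matrix (subjects x voxels) or a
#'   [feature_matrix()].
#' @param stats data.frame from [component_group_ttest()] (columns
#'   `component`, `p`, `significant`) for this modality.
#' @param S_k source matrix, components x voxels.
#' @param tau Z threshold (default 3.5).
#' @param top_k keep only the `top_k` smallest-p significant components
#'   (default: all significant ones).
#' @param modality_name name carried into the result.
#'
#' @return A list of class `masked_feature_set`: `modality`, `data`
#'   (N x V_sel), `voxel_idx` (union mask, ascending voxel order),
#'   `components` (selected component indices), `tau`.
#' @export
build_masked_features <- function(X_k, stats, S_k, tau = 3.5, top_k = NULL,
                                  modality_name = NULL) {
  x <- if (inherits(X_k, "feature_matrix")) X_k$data else as.matrix(X_k)
  if (is.null(modality_name)) {
    modality_name <- if (inherits(X_k, "feature_matrix")) X_k$modality else "mod"
  }
  S_k <- as.matrix(S_k)
  sig <- stats$component[stats$significant]
  if (length(sig) == 0) {
    stop_precondition(sprintf(
      "no discriminative component for modality '%s'", modality_name))
  }
  if (!is.null(top_k)) {
    psig <- stats$p[match(sig, stats$component)]
    sig <- sig[order(psig)][seq_len(min(top_k, length(sig)))]
  }
  idx <- integer(0)
  for (m in sig) {
    idx <- union(idx, threshold_mask(component_zmap(S_k[m, ]), tau))
  }
  idx <- sort(idx)
  if (length(idx) == 0) {
    stop_data(sprintf(
      "empty union mask for modality '%s' at |Z| > %g; lower tau",
      modality_name, tau))
  }
  structure(list(modality = modality_name,
                 data = x[, idx, drop = FALSE],
                 voxel_idx = idx,
                 components = sort(sig),
                 tau = tau),
            class = "masked_feature_set")
}

#' @export
print.masked_feature_set <- function(x, ...) {
  cat(sprintf(
    "<masked_feature_set '%s': %d x %d (components %s, |Z| > %g)>\n",
    x$modality, nrow(x$data), ncol(x$data),
    paste(x$components, collapse = ","), x$tau))
  invisible(x)
}

#' All non-empty modality combinations
#'
#' @param modalities character vector of modality names (1 to 8).
#' @return List of character vectors: all `2^n - 1` non-empty subsets,
#'   ordered by size then lexicographically.
#' @export
enumerate_combinations <- function(modalities) {
  n <- length(modalities)
  if (n < 1 || n > 8) stop_precondition("1 to 8 modalities supported")
  out <- list()
  for (size in seq_len(n)) {
    subs <- utils::combn(sort(modalities), size, simplify = FALSE)
    subs <- subs[order(vapply(subs, paste, "", collapse = "\r"))]
    out <- c(out, subs)
  }
  out
}

# default hyperparameter grids, selected by 10-fold CV on the training half
.default_grids <- function(n_features) {
  list(`linear-SVM` = list(cost = c(0.01, 0.1, 1, 10)),
       `RBF-SVM` = expand.grid(cost = c(0.1, 1, 10),
                               gamma = c(0.1, 1, 10) / max(n_features, 1)),
       kNN = list(k = c(1, 3, 5, 7, 9)),
       `Gaussian-naive-Bayes` = list())
}

# train on (xtr, ytr) with given hyperparameters, predict labels for xte
.fit_predict <- function(algo, xtr, ytr, xte, hp) {
  if (algo == "linear-SVM") {
    fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = hp$cost,
                      scale = FALSE)
    stats::predict(fit, xte)
  } else if (algo == "RBF-SVM") {
    fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = hp$cost,
                      gamma = hp$gamma, scale = FALSE)
    stats::predict(fit, xte)
  } else if (algo == "kNN") {
    class::knn(xtr, xte, ytr, k = hp$k)
  } else if (algo == "Gaussian-naive-Bayes") {
    fit <- e1071::naiveBayes(xtr, ytr)
    stats::predict(fit, xte)
  } else stop_precondition("unknown algorithm: ", algo)
}

# pick hyperparameters by k-fold CV accuracy on the training half
.cv_select <- function(algo, xtr, ytr, grid, folds) {
  if (algo == "Gaussian-naive-Bayes") return(list())
  grid_df <- if (is.data.frame(grid)) grid else expand.grid(grid)
  if (nrow(grid_df) == 1) return(as.list(grid_df[1, , drop = FALSE]))
  n <- nrow(xtr)
  fold_id <- integer(n)
  for (lv in levels(ytr)) {
    i <- which(ytr == lv)
    fold_id[i] <- rep_len(seq_len(folds), length(i))[sample.int(length(i))]
  }
  acc <- vapply(seq_len(nrow(grid_df)), function(g) {
    hp <- as.list(grid_df[g, , drop = FALSE])
    correct <- 0
    for (f in seq_len(folds)) {
      te <- fold_id == f
      if (!any(te) || length(unique(ytr[!te])) < 2) next
      pred <- .fit_predict(algo, xtr[!te, , drop = FALSE], ytr[!te],
                           xtr[te, , drop = FALSE], hp)
      correct <- correct + sum(pred == ytr[te])
    }
    correct / n
  }, numeric(1))
  as.list(grid_df[which.max(acc), , drop = FALSE])
}

#' Repeated split-half classification over modality combinations
#'
#' Implements the evaluation protocol for masked multimodal features: for
#' every non-empty modality combination (features concatenated
#' column-wise) and every algorithm, repeat `n_repetitions` times a
#' stratified random 50/50 split; standardize features by the training
#' half's mean/sd; choose hyperparameters by `cv_folds`-fold
#' cross-validation within the training half; train on the full training
#' half and score accuracy on the held-out half. The same split sequence
#' (derived from the master seed) is reused across combinations and
#' algorithms so comparisons are paired.
#'
#' Note: when the masks defining the feature sets were derived from the
#' same subjects being classified, accuracies are optimistically biased
#' (circular analysis); the report records this via `mask_provenance`.
#'
#' @param feature_sets list of `masked_feature_set` objects (same subject
#'   order).
#' @param groups two-level labels in subject order.
#' @param algorithms subset of `c("linear-SVM", "RBF-SVM", "kNN",
#'   "Gaussian-naive-Bayes")`.
#' @param n_repetitions number of split-half repetitions (default 1000).
#' @param seed master seed; the report is bit-reproducible given it.
#' @param cv_folds folds for hyperparameter selection (default 10).
#' @param grids optional named list overriding the default hyperparameter
#'   grids.
#' @param mask_provenance `"same-data"` (default, the honest label when
#'   masks come from the classified cohort) or `"independent"`.
#'
#' @return A list of class `classification_report`: `summary` (data.frame:
#'   combination, algorithm, mean_accuracy, max_accuracy, n_repetitions),
#'   `accuracies` (list of per-repetition vectors), `seed`,
#'   `mask_provenance`.
#' @export
run_classification <- function(feature_sets, groups,
                               algorithms = c("linear-SVM", "RBF-SVM",
                                              "kNN",
                                              "Gaussian-naive-Bayes"),
                               n_repetitions = 1000, seed = 1L,
                               cv_folds = 10, grids = NULL,
                               mask_provenance = "same-data") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop_precondition("exactly two classes required")
  if (n_repetitions < 1) stop_precondition("n_repetitions must be >= 1")
  n <- length(groups)
  if (any(vapply(feature_sets, function(f) nrow(f$data), 1L) != n)) {
    stop_dim("feature sets and groups disagree on subject count")
  }
  mod_names <- vapply(feature_sets, `[[`, "", "modality")
  names(feature_sets) <- mod_names
  combos <- enumerate_combinations(mod_names)

  with_seed(seed, {
    # pre-draw the stratified split sequence once; reused everywhere
    splits <- lapply(seq_len(n_repetitions), function(r) {
      tr <- logical(n)
      for (lv in levels(groups)) {
        i <- which(groups == lv)
        tr[sample(i, floor(length(i) / 2))] <- TRUE
      }
      tr
    })
    cv_seeds <- sample.int(.Machine$integer.max, n_repetitions)

    rows <- list(); accs <- list()
    for (combo in combos) {
      X <- do.call(cbind, lapply(feature_sets[combo], function(f) f$data))
      grid_set <- if (is.null(grids)) .default_grids(ncol(X)) else grids
      for (algo in algorithms) {
        acc <- numeric(n_repetitions)
        for (r in seq_len(n_repetitions)) {
          tr <- splits[[r]]
          if (length(unique(groups[tr])) < 2) {
            # cannot happen with stratified splits; kept as a guard
            tr <- !tr
          }
          mu <- colMeans(X[tr, , drop = FALSE])
          sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
          sdv[sdv < 1e-12] <- 1
          Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
          xtr <- Xs[tr, , drop = FALSE]; xte <- Xs[!tr, , drop = FALSE]
          set.seed(cv_seeds[r])
          hp <- .cv_select(algo, xtr, groups[tr], grid_set[[algo]],
                           cv_folds)
          pred <- .fit_predict(algo, xtr, groups[tr], xte, hp)
          acc[r] <- mean(pred == groups[!tr])
        }
        key <- paste(paste(combo, collapse = "+"), algo, sep = " | ")
        accs[[key]] <- acc
        rows[[key]] <- data.frame(combination = paste(combo, collapse = "+"),
                                  algorithm = algo,
                                  mean_accuracy = mean(acc),
                                  max_accuracy = max(acc),
                                  n_repetitions = n_repetitions)
      }
    }
    structure(list(summary = do.call(rbind, c(rows,
                                              list(make.row.names = FALSE))),
                   accuracies = accs,
                   seed = as.integer(seed),
                   mask_provenance = mask_provenance),
              class = "classification_report")
  })
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report: %d combination x algorithm cells, seed %d>\n",
              nrow(x$summary), x$seed))
  if (identical(x$mask_provenance, "same-data")) {
    cat("NOTE: masks derive from the classified cohort itself;",
        "accuracies are optimistically biased.\n")
  }
  print(x$summary, digits = 3)
  invisible(x)
}
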