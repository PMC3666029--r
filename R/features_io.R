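#' Construct a modality feature matrix
#'
#' A feature matrix holds one modality's subjects-by-voxels data `X_k`
#' together with the voxel mask that maps its columns back onto a reference
#' 3-D grid. It is the unit of input to [fuse()].
#'
#' @param data numeric matrix, subjects (rows) by masked voxels (columns).
#' @param modality short modality name, e.g. `"ALFF"`, `"FA"`, `"GM"`.
#' @param mask_coords integer matrix with one row per column of `data` and
#'   three columns (1-based i, j, k voxel indices into the reference grid),
#'   in raster order (first axis fastest). Defaults to a flat 1-D layout.
#' @param grid_shape integer vector of length 3, the reference grid
#'   dimensions.
#' @param affine 4x4 voxel-to-world transform; defaults to identity.
#' @param subject_ids character vector of unique subject identifiers, one
#'   per row of `data`. Subject order must be identical across all
#'   modalities of a study.
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(data, modality,
                           mask_coords = NULL,
                           grid_shape = NULL,
                           affine = diag(4),
                           subject_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_data("feature data must be numeric")
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop_data(sprintf(
      "non-finite value for subject row %d at masked voxel %d in modality '%s'",
      bad[1], bad[2], modality))
  }
  n <- nrow(data); l <- ncol(data)
  if (n < 2) stop_precondition("a feature matrix needs at least 2 subjects")
  if (l < 1) stop_precondition("a feature matrix needs at least 1 voxel")
  if (is.null(grid_shape)) grid_shape <- c(l, 1L, 1L)
  grid_shape <- as.integer(grid_shape)
  if (is.null(mask_coords)) {
    mask_coords <- cbind(seq_len(l), 1L, 1L)
  }
  mask_coords <- as.matrix(mask_coords)
  storage.mode(mask_coords) <- "integer"
  if (nrow(mask_coords) != l || ncol(mask_coords) != 3) {
    stop_dim("mask_coords must be a ", l, " x 3 integer matrix")
  }
  if (any(mask_coords < 1) ||
      any(sweep(mask_coords, 2, grid_shape, ">"))) {
    stop_data("mask_coords outside grid_shape")
  }
  lin <- (mask_coords[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
    (mask_coords[, 2] - 1L) * grid_shape[1] + mask_coords[, 1]
  if (anyDuplicated(lin)) stop_data("mask_coords contains duplicate voxels")
  if (is.null(subject_ids)) subject_ids <- sprintf("subj%03d", seq_len(n))
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n || anyDuplicated(subject_ids)) {
    stop_data("subject_ids must be unique, one per data row")
  }
  structure(list(modality = as.character(modality),
                 data = unname(data),
                 mask_coords = unname(mask_coords),
                 grid_shape = grid_shape,
                 affine = affine,
                 subject_ids = subject_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s': %d subjects x %d voxels, grid %s>\n",
              x$modality, nrow(x$data), ncol(x$data),
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$data)

#' Load per-subject 3-D feature maps into a feature matrix
#'
#' Reads one NIfTI volume per subject, checks that all volumes share the
#' mask's grid and affine, and stacks the masked voxel values (raster order
#' of the mask coordinates) into a subjects-by-voxels matrix.
#'
#' @param paths character vector of NIfTI volume paths, in subject order.
#' @param mask path to a NIfTI mask volume (non-zero voxels are kept), or
#'   an integer matrix of 1-based voxel coordinates (rows = voxels, columns
#'   = i, j, k) together with `grid_shape`.
#' @param modality modality name for the resulting matrix.
#' @param subject_ids optional subject identifiers; defaults to file
#'   basenames without extension.
#' @param grid_shape required when `mask` is a coordinate matrix.
#'
#' @return A [feature_matrix()].
#' @export
load_feature_maps <- function(paths, mask, modality,
                              subject_ids = NULL, grid_shape = NULL) {
  if (length(paths) < 1) stop_precondition("no volumes given")
  if (is.character(mask)) {
    mvol <- RNifti::readNifti(mask)
    grid_shape <- c(dim(mvol), 1L, 1L)[1:3]   # pad dropped singleton dims
    mask_affine <- unclass(RNifti::xform(mvol))
    mask_coords <- which(array(as.numeric(mvol) != 0, dim = grid_shape),
                         arr.ind = TRUE)
  } else {
    if (is.null(grid_shape)) {
      stop_precondition("grid_shape required with an explicit coordinate mask")
    }
    mask_coords <- as.matrix(mask)
    mask_affine <- NULL
  }
  if (nrow(mask_coords) == 0) stop_precondition("mask is empty")
  # raster order: first axis fastest
  ord <- order(mask_coords[, 3], mask_coords[, 2], mask_coords[, 1])
  mask_coords <- mask_coords[ord, , drop = FALSE]

  n <- length(paths)
  dat <- matrix(NA_real_, n, nrow(mask_coords))
  affine <- NULL
  for (i in seq_len(n)) {
    vol <- RNifti::readNifti(paths[i])
    vdim <- c(dim(vol), 1L, 1L)[1:3]
    if (!identical(as.integer(vdim), as.integer(grid_shape))) {
      stop_dim(sprintf("volume '%s' has grid %s but the mask has %s",
                       paths[i], paste(vdim, collapse = "x"),
                       paste(grid_shape, collapse = "x")))
    }
    vaff <- unclass(RNifti::xform(vol))
    if (!is.null(mask_affine) && max(abs(vaff - mask_affine)) > 1e-4) {
      stop_dim(sprintf("volume '%s' affine differs from the mask affine",
                       paths[i]))
    }
    if (is.null(affine)) affine <- vaff
    vals <- array(as.numeric(vol), dim = grid_shape)[mask_coords]
    if (any(!is.finite(vals))) {
      v <- which(!is.finite(vals))[1]
      stop_data(sprintf(
        "subject '%s' has a non-finite value inside the mask (voxel %d)",
        paths[i], v))
    }
    dat[i, ] <- vals
  }
  if (is.null(subject_ids)) {
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  }
  feature_matrix(dat, modality, mask_coords = mask_coords,
                 grid_shape = grid_shape, affine = affine,
                 subject_ids = subject_ids)
}

#' Equalize the mean square across modalities
#'
#' Rescales each modality so the mean of its squared entries (over all
#' subjects and voxels) equals a common target. Multiplication by a single
#' per-modality factor preserves all within-modality value ratios; only the
#' relative scaling between modalities changes, so no modality dominates
#' the joint decomposition by raw units alone.
#'
#' @param mats list of [feature_matrix()] objects.
#' @param target_msq positive target mean square (default 1).
#'
#' @return A list with `mats` (rescaled feature matrices) and `records`
#'   (one data.frame row per modality: `modality`, `factor`, `pre_msq`,
#'   `post_msq`).
#' @export
normalize_modalities <- function(mats, target_msq = 1) {
  stopifnot(target_msq > 0)
  records <- data.frame(modality = character(0), factor = numeric(0),
                        pre_msq = numeric(0), post_msq = numeric(0))
  out <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    pre <- mean(m$data^2)
    if (pre <= 0) {
      stop_data(sprintf("modality '%s' is all zeros; cannot normalize",
                        m$modality))
    }
    f <- sqrt(target_msq / pre)
    m$data <- m$data * f
    out[[i]] <- m
    records <- rbind(records,
                     data.frame(modality = m$modality, factor = f,
                                pre_msq = pre, post_msq = mean(m$data^2)))
  }
  list(mats = out, records = records)
}

#' Write component maps back to NIfTI volumes
#'
#' Each row of `maps` is written as one 3-D volume: masked voxels carry the
#' row values, voxels outside the mask are 0. Volumes are written as
#' float32 NIfTI-1.
#'
#' @param maps numeric matrix, components (rows) by masked voxels.
#' @param mask_coords,grid_shape,affine mask geometry as in
#'   [feature_matrix()].
#' @param out_prefix path prefix; component `m` goes to
#'   `<out_prefix>_comp<m>.nii.gz`.
#'
#' @return Invisibly, the vector of written file paths.
#' @export
save_component_maps <- function(maps, mask_coords, grid_shape, affine,
                                out_prefix) {
  maps <- as.matrix(maps)
  mask_coords <- as.matrix(mask_coords)
  if (ncol(maps) != nrow(mask_coords)) {
    stop_dim(sprintf("maps have %d columns but the mask has %d voxels",
                     ncol(maps), nrow(mask_coords)))
  }
  paths <- character(nrow(maps))
  for (m in seq_len(nrow(maps))) {
    vol <- array(0, dim = grid_shape)
    vol[mask_coords] <- maps[m, ]
    img <- RNifti::asNifti(vol, datatype = "float")
    if (!is.null(affine)) RNifti::qform(img) <- structure(affine, code = 2L)
    paths[m] <- sprintf("%s_comp%02d.nii.gz", out_prefix, m)
    RNifti::writeNifti(img, paths[m])
  }
  invisible(paths)
}
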