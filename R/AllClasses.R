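#' @useDynLib patreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict
#' @import methods
NULL

MODALITIES <- c("GM", "WM", "PET")

#' Template-space sampling grid
#'
#' Describes the common voxel lattice all volumes of a cohort live on: the
#' array shape in voxels, the voxel size in mm per axis, and the 4x4 affine
#' mapping 0-based voxel indices to template (world) coordinates.
#'
#' @slot shape integer(3), voxels per axis (all >= 1).
#' @slot voxelSize numeric(3), mm per axis (all > 0).
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("VolumeGrid",
  representation(shape = "integer", voxelSize = "numeric", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  msg <- NULL
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 integers >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  if (is.null(msg)) TRUE else msg
})

#' Construct a VolumeGrid
#'
#' @param shape integer(3) array shape in voxels.
#' @param voxelSize voxel size in mm, recycled to length 3.
#' @param affine optional 4x4 voxel-to-world matrix; default is a diagonal
#'   scaling by `voxelSize` (0-based indexing convention).
#' @return A [VolumeGrid-class] object.
#' @examples
#' VolumeGrid(c(32, 32, 32), voxelSize = 2)
#' @export
VolumeGrid <- function(shape, voxelSize = 1, affine = NULL) {
  shape <- as.integer(shape)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxelSize, 1))
  }
  new("VolumeGrid", shape = shape, voxelSize = voxelSize, affine = affine)
}

#' @describeIn VolumeGrid Compare two grids for equality (shape, voxel size,
#'   affine to 1e-6).
#' @param g1,g2 `VolumeGrid` objects.
#' @export
sameGrid <- function(g1, g2) {
  identical(g1@shape, g2@shape) &&
    isTRUE(all.equal(g1@voxelSize, g2@voxelSize, tolerance = 1e-6)) &&
    isTRUE(all.equal(g1@affine, g2@affine, tolerance = 1e-6))
}

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@shape, collapse = " x "), "voxels,",
      paste(signif(object@voxelSize, 4), collapse = " x "), "mm\n")
})

#' Scalar brain volume in template space
#'
#' A 3-D scalar field on a [VolumeGrid-class]: tissue density for GM/WM
#' (RAVENS-style regional volumetric maps) or normalized flow for PET.
#'
#' @slot grid the sampling grid.
#' @slot data numeric 3-D array matching the grid shape.
#' @slot modality one of `"GM"`, `"WM"`, `"PET"`.
#' @export
setClass("BrainVolume",
  representation(grid = "VolumeGrid", data = "array", modality = "character"))

setValidity("BrainVolume", function(object) {
  msg <- NULL
  if (!identical(dim(object@data), as.integer(object@grid@shape)))
    msg <- c(msg, "data dimensions must match grid shape")
  if (length(object@modality) != 1L || !object@modality %in% MODALITIES)
    msg <- c(msg, "modality must be one of GM, WM, PET")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BrainVolume
#'
#' @param data numeric 3-D array.
#' @param grid a [VolumeGrid-class]; default derived from `dim(data)` with
#'   1 mm voxels.
#' @param modality `"GM"`, `"WM"` or `"PET"`.
#' @return A [BrainVolume-class].
#' @export
BrainVolume <- function(data, grid = NULL, modality = "GM") {
  data <- as.array(data)
  if (is.null(grid)) grid <- VolumeGrid(dim(data))
  new("BrainVolume", grid = grid, data = data, modality = modality)
}

#' Binary brain mask
#'
#' The analysis mask shared by all subjects and modalities of a cohort.
#' Statistics are computed over mask voxels only; outputs are 0 outside.
#'
#' @slot grid the sampling grid.
#' @slot data logical 3-D array with at least one `TRUE` voxel.
#' @export
setClass("BrainMask",
  representation(grid = "VolumeGrid", data = "array"))

setValidity("BrainMask", function(object) {
  msg <- NULL
  if (!identical(dim(object@data), as.integer(object@grid@shape)))
    msg <- c(msg, "data dimensions must match grid shape")
  if (!is.logical(object@data))
    msg <- c(msg, "mask data must be logical")
  if (!any(object@data))
    msg <- c(msg, "mask must contain at least one TRUE voxel")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BrainMask
#'
#' @param data logical (or coercible) 3-D array.
#' @param grid a [VolumeGrid-class]; default from `dim(data)`.
#' @return A [BrainMask-class].
#' @export
BrainMask <- function(data, grid = NULL) {
  data <- array(as.logical(data), dim = dim(as.array(data)))
  if (is.null(grid)) grid <- VolumeGrid(dim(data))
  new("BrainMask", grid = grid, data = data)
}

#' Regional cluster atlas
#'
#' Labelled partition of the brain mask into 26-connected regional voxel
#' clusters for one modality, as produced by [watershedCluster()]. Label 0 is
#' background; labels 1..K partition the mask exactly.
#'
#' @slot grid the sampling grid.
#' @slot labels integer 3-D array of cluster labels.
#' @slot clusters data.frame with columns `label`, `modality`, `nVoxels`,
#'   `meanAbsR` (mean absolute correlation of the cluster's voxels).
#' @export
setClass("ClusterAtlas",
  representation(grid = "VolumeGrid", labels = "array", clusters = "data.frame"))

setValidity("ClusterAtlas", function(object) {
  msg <- NULL
  if (!identical(dim(object@labels), as.integer(object@grid@shape)))
    msg <- c(msg, "labels dimensions must match grid shape")
  k <- nrow(object@clusters)
  labs <- object@labels[object@labels > 0L]
  if (k > 0L && !setequal(unique(as.integer(labs)), object@clusters$label))
    msg <- c(msg, "cluster table must list exactly the labels present")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ClusterAtlas", function(object) {
  cat("ClusterAtlas:", nrow(object@clusters), "clusters (",
      object@clusters$modality[1], ") on ",
      paste(object@grid@shape, collapse = "x"), " grid\n", sep = "")
})

#' Subjects-by-regions feature matrix
#'
#' Rows are subjects, columns regional features (per-cluster mean voxel
#' values), with modality/cluster provenance per column.
#'
#' @slot values numeric matrix, subjects x features.
#' @slot features data.frame with columns `modality`, `cluster` (one row per
#'   column of `values`).
#' @slot subjects character subject identifiers.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", features = "data.frame",
                 subjects = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  if (nrow(object@features) != ncol(object@values))
    msg <- c(msg, "one feature row per value column required")
  if (length(object@subjects) != nrow(object@values))
    msg <- c(msg, "one subject per value row required")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (anyDuplicated(paste(object@features$modality, object@features$cluster)))
    msg <- c(msg, "feature provenance (modality, cluster) must be unique")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "subjects x",
      ncol(object@values), "features (",
      paste(unique(object@features$modality), collapse = ", "), ")\n")
})

#' Relevance vector regression model
#'
#' Kernel regression with independent Gaussian priors on basis weights whose
#' precisions are optimized by evidence maximization; most precisions diverge,
#' leaving a sparse set of relevance vectors.
#'
#' @slot X standardized training design points (rows).
#' @slot center,scale per-feature standardization parameters from training.
#' @slot kernel list with `kind` ("rbf" or "linear"), `gamma`, `includeBias`.
#' @slot relevance integer indices into training rows of surviving kernel
#'   basis functions (0 denotes the bias term).
#' @slot mu posterior weight means for the surviving basis set.
#' @slot alpha weight precisions for the surviving basis set.
#' @slot Sigma posterior weight covariance.
#' @slot sigma2 noise variance.
#' @slot converged,iterations fit diagnostics.
#' @slot logEvidence per-iteration log marginal likelihood.
#' @slot interceptOnly TRUE when every kernel basis was pruned and the model
#'   fell back to predicting the training mean.
#' @slot yMean training-target mean (used by the intercept-only fallback).
#' @export
setClass("RVRModel",
  representation(X = "matrix", center = "numeric", scale = "numeric",
                 kernel = "list", relevance = "integer", mu = "numeric",
                 alpha = "numeric", Sigma = "matrix", sigma2 = "numeric",
                 converged = "logical", iterations = "integer",
                 logEvidence = "numeric", interceptOnly = "logical",
                 yMean = "numeric"))

setValidity("RVRModel", function(object) {
  msg <- NULL
  if (!object@interceptOnly) {
    if (any(object@alpha <= 0)) msg <- c(msg, "alpha must be positive")
    if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be positive")
    if (length(object@mu) != length(object@relevance))
      msg <- c(msg, "mu and relevance set must align")
    if (any(object@relevance > nrow(object@X)))
      msg <- c(msg, "relevance vectors must be training points")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "RVRModel", function(object) {
  if (object@interceptOnly) {
    cat("RVRModel: intercept-only fallback (all basis functions pruned)\n")
  } else {
    nrv <- sum(object@relevance > 0L)
    cat("RVRModel:", object@kernel$kind, "kernel,", nrv, "relevance vectors /",
        nrow(object@X), "training points; sigma2 =",
        signif(object@sigma2, 4), "\n")
  }
})

#' Aligned multi-modal cohort sample
#'
#' Subjects with one volume per modality on a shared grid and mask, a score
#' table of raw neuropsychological tests and covariates, battery definitions,
#' and (for synthetic cohorts) the generating ground truth.
#'
#' @slot grid,mask shared sampling grid and analysis mask.
#' @slot data named list (by modality) of 4-D arrays `[x, y, z, subject]`.
#' @slot subjects character subject ids, aligned with `scores` rows and the
#'   fourth array dimension.
#' @slot scores data.frame: `subject_id`, `age`, `sex`, `icv`, then one column
#'   per raw test.
#' @slot batteries named list: domain -> character vector of test columns.
#' @slot groundTruth list (possibly empty): `z`, `labels` (per-modality
#'   region-label arrays), `beta` (per-modality per-region effects), `icv`.
#' @export
setClass("CohortSample",
  representation(grid = "VolumeGrid", mask = "BrainMask", data = "list",
                 subjects = "character", scores = "data.frame",
                 batteries = "list", groundTruth = "list"))

setValidity("CohortSample", function(object) {
  msg <- NULL
  for (m in names(object@data)) {
    d <- dim(object@data[[m]])
    if (!identical(d[1:3], as.integer(object@grid@shape)))
      msg <- c(msg, sprintf("%s volumes do not match the grid", m))
    if (d[4] != length(object@subjects))
      msg <- c(msg, sprintf("%s volume count does not match subjects", m))
  }
  if (!sameGrid(object@grid, object@mask@grid))
    msg <- c(msg, "mask grid differs from cohort grid")
  if (!identical(object@scores$subject_id, object@subjects))
    msg <- c(msg, "score table rows must align with subjects")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortSample", function(object) {
  cat("CohortSample:", length(object@subjects), "subjects,",
      paste(names(object@data), collapse = "/"), "on",
      paste(object@grid@shape, collapse = "x"), "grid;",
      length(object@batteries), "domain batteries\n")
})

#' Leave-k-out cross-validation result
#'
#' Per-split selection/fit bookkeeping plus per-subject averaged left-out
#' predictions for one cognitive domain and modality set.
#'
#' @slot domain cognitive domain name.
#' @slot modalities modalities used by the model.
#' @slot predictions data.frame: `subject_id`, `actual`, `predicted`,
#'   `coverage` (number of splits the subject was left out of).
#' @slot valMSE numeric validation MSE per split.
#' @slot splits list of per-split records (train/validation indices, selected
#'   features, RFE trace, per-feature contributions).
#' @slot contribution per-modality voxelwise mean spatial difference map
#'   before joint normalization (list of 3-D arrays).
#' @export
setClass("CVResult",
  representation(domain = "character", modalities = "character",
                 grid = "VolumeGrid", mask = "BrainMask",
                 predictions = "data.frame", valMSE = "numeric",
                 splits = "list", contribution = "list"))

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", object@domain, "~",
      paste(object@modalities, collapse = "+"), "|",
      length(object@splits), "splits | mean val MSE",
      signif(mean(object@valMSE), 4), "| r(pred, actual) =",
      signif(stats::cor(object@predictions$predicted,
                        object@predictions$actual), 3), "\n")
})

#' Voxelwise contribution map
#'
#' Per-modality voxel volumes of regression contributions, min-max normalized
#' jointly across modalities to [0, 1] so cross-modality comparison is
#' meaningful; zero outside the mask.
#'
#' @slot grid sampling grid.
#' @slot maps named list (by modality) of 3-D arrays in [0, 1].
#' @slot overlayThreshold display cutoff (computation never thresholds).
#' @export
setClass("ContributionMap",
  representation(grid = "VolumeGrid", maps = "list",
                 overlayThreshold = "numeric"))

setValidity("ContributionMap", function(object) {
  msg <- NULL
  for (m in names(object@maps)) {
    v <- object@maps[[m]]
    if (!identical(dim(v), as.integer(object@grid@shape)))
      msg <- c(msg, sprintf("%s map does not match the grid", m))
    if (any(v < -1e-12 | v > 1 + 1e-12))
      msg <- c(msg, sprintf("%s map must lie in [0, 1]", m))
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ContributionMap", function(object) {
  cat("ContributionMap:", paste(names(object@maps), collapse = "/"),
      "on", paste(object@grid@shape, collapse = "x"),
      "grid; overlay threshold", object@overlayThreshold, "\n")
})
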