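#' Per-modality smoothing kernel widths
#'
#' Full-widths at half maximum, in mm, of the Gaussian filters applied to
#' each modality. Structural density maps are conventionally smoothed at
#' 8 mm; the lower-resolution PET flow maps at 12 mm.
#'
#' @param gm,wm,pet FWHM in mm per modality (all > 0).
#' @return Named list used by [smoothVolume()] and [preprocessCohort()].
#' @export
smoothingConfig <- function(gm = 8, wm = 8, pet = 12) {
  cfg <- list(GM = gm, WM = wm, PET = pet)
  if (any(unlist(cfg) <= 0)) stop("fwhm_mm must be positive")
  cfg
}

# 1-D Gaussian kernel, unit sum; radius 4 sigma
.gaussKernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

# reflect out-of-range index into [1, n] (half-sample symmetric boundary)
.reflectIndex <- function(i, n) {
  while (any(bad <- i < 1L | i > n)) {
    i[bad & i < 1L] <- 1L - i[bad & i < 1L]
    i[bad & i > n] <- 2L * n + 1L - i[bad & i > n]
  }
  i
}

# n x n convolution operator with reflecting boundary for kernel k
.convOperator <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    j <- .reflectIndex(seq_len(n) + o, n)
    C[cbind(seq_len(n), j)] <- C[cbind(seq_len(n), j)] + k[o + r + 1L]
  }
  C
}

# apply an n_out x n_in linear operator along one array axis
.applyAxis <- function(a, op, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  out <- op %*% matrix(ap, nrow = d[axis])
  dn <- d[perm]
  dn[1] <- nrow(op)
  array(aperm(array(out, dim = dn), order(perm)),
        dim = replace(d, axis, nrow(op)))
}

# separable Gaussian smoothing of a 3-D array; sigma in voxels per axis
.smoothArray <- function(a, sigma) {
  for (axis in 1:3) {
    if (sigma[axis] > 1e-8) {
      a <- .applyAxis(a, .convOperator(dim(a)[axis], .gaussKernel1d(sigma[axis])),
                      axis)
    }
  }
  a
}

#' Smooth a brain volume
#'
#' Separable Gaussian filter with per-axis standard deviation
#' `sigma = fwhm / (voxelSize * sqrt(8 log 2))` voxels and a reflecting
#' boundary, which preserves the total intensity of interior structure.
#'
#' @param v a [BrainVolume-class].
#' @param cfg a [smoothingConfig()] list (FWHM looked up by `modality(v)`),
#'   or a single FWHM in mm.
#' @return The smoothed [BrainVolume-class].
#' @examples
#' v <- BrainVolume(array(rnorm(16^3)^2, c(16, 16, 16)),
#'                  VolumeGrid(c(16, 16, 16), 2))
#' s <- smoothVolume(v, smoothingConfig())
#' @export
smoothVolume <- function(v, cfg = smoothingConfig()) {
  fwhm <- if (is.list(cfg)) cfg[[v@modality]] else cfg
  if (is.null(fwhm) || !is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be defined and positive for modality ", v@modality)
  sigma <- fwhm / (v@grid@voxelSize * sqrt(8 * log(2)))
  BrainVolume(.smoothArray(v@data, sigma), grid = v@grid,
              modality = v@modality)
}

#' Intracranial-volume normalization
#'
#' Rescales a tissue-density map to a common head size by multiplying every
#' voxel by `referenceIcv / icv`, removing global differences in intracranial
#' volume between subjects.
#'
#' @param v a [BrainVolume-class].
#' @param icv the subject's intracranial volume in mm^3 (> 0).
#' @param referenceIcv the cohort reference intracranial volume in mm^3.
#' @return The normalized [BrainVolume-class].
#' @export
icvNormalize <- function(v, icv, referenceIcv = 1.5e6) {
  if (!is.finite(icv) || icv <= 0) stop("icv must be positive")
  if (!is.finite(referenceIcv) || referenceIcv <= 0)
    stop("referenceIcv must be positive")
  BrainVolume(v@data * (referenceIcv / icv), grid = v@grid,
              modality = v@modality)
}

# block-average operator along one axis; trailing partial block averaged
.blockOperator <- function(n, factor) {
  g <- ceiling(seq_len(n) / factor)
  nOut <- max(g)
  A <- matrix(0, nOut, n)
  A[cbind(g, seq_len(n))] <- 1
  A / rowSums(A)
}

#' Block-mean downsampling
#'
#' Averages non-overlapping `factor^3` blocks. When `factor` divides the
#' shape, total intensity times voxel volume is preserved exactly; trailing
#' partial blocks are averaged over the voxels present.
#'
#' @param v a [BrainVolume-class].
#' @param factor positive integer downsampling factor.
#' @return A [BrainVolume-class] on the coarser grid.
#' @export
downsampleVolume <- function(v, factor = 2L) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(v)
  a <- v@data
  for (axis in 1:3) {
    a <- .applyAxis(a, .blockOperator(dim(a)[axis], factor), axis)
  }
  newShape <- dim(a)
  aff <- v@grid@affine
  # new voxel i (0-based) is centred on old voxel factor*i + (factor-1)/2
  aff[, 4] <- aff[, 4] + aff[, 1:3] %*% rep((factor - 1) / 2, 3)
  aff[, 1:3] <- aff[, 1:3] * factor
  BrainVolume(a, grid = VolumeGrid(newShape, v@grid@voxelSize * factor,
                                   affine = aff),
              modality = v@modality)
}

#' Preprocess a cohort in place of the scanner-side pipeline
#'
#' Applies the preprocessing the analysis owns: intracranial-volume
#' normalization of every subject's volumes (using the `icv` column of the
#' score table) followed by per-modality Gaussian smoothing, and optional
#' block-mean downsampling. Registration, segmentation and mass-preserving
#' warping are assumed already done: all volumes must share the cohort grid.
#'
#' @param cohort a [CohortSample-class].
#' @param smoothing a [smoothingConfig()] list, or `NULL` to skip smoothing.
#' @param referenceIcv reference intracranial volume in mm^3.
#' @param downsampleFactor integer >= 1 (1 = keep resolution).
#' @return The preprocessed [CohortSample-class].
#' @export
preprocessCohort <- function(cohort, smoothing = smoothingConfig(),
                             referenceIcv = 1.5e6, downsampleFactor = 1L) {
  icv <- cohort@scores$icv
  out <- cohort@data
  for (m in names(out)) {
    arr <- out[[m]]
    sigma <- if (is.null(smoothing)) c(0, 0, 0) else
      smoothing[[m]] / (cohort@grid@voxelSize * sqrt(8 * log(2)))
    for (s in seq_along(cohort@subjects)) {
      v <- arr[, , , s] * (referenceIcv / icv[s])
      if (!is.null(smoothing)) v <- .smoothArray(v, sigma)
      arr[, , , s] <- v
    }
    out[[m]] <- arr
  }
  cohort@data <- out
  if (downsampleFactor > 1L) {
    ref <- downsampleVolume(BrainVolume(cohort@data[[1]][, , , 1],
                                        grid = cohort@grid),
                            downsampleFactor)
    ds <- lapply(cohort@data, function(arr) {
      n <- dim(arr)[4]
      outArr <- array(0, dim = c(ref@grid@shape, n))
      for (s in seq_len(n)) {
        outArr[, , , s] <- downsampleVolume(
          BrainVolume(arr[, , , s], grid = cohort@grid),
          downsampleFactor)@data
      }
      outArr
    })
    maskDs <- downsampleVolume(BrainVolume(
      array(as.numeric(cohort@mask@data), dim = dim(cohort@mask@data)),
      grid = cohort@grid), downsampleFactor)
    cohort@data <- ds
    cohort@grid <- ref@grid
    cohort@mask <- BrainMask(maskDs@data >= 0.5, grid = ref@grid)
    if (length(cohort@groundTruth)) {
      cohort@groundTruth$note <-
        "ground-truth label volumes remain at generator resolution"
    }
  }
  methods::validObject(cohort)
  cohort
}
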