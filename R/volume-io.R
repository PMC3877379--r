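#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a [BrainVolume-class]. The sampling grid (shape,
#' voxel size, affine) is taken from the header; when `expectedGrid` is given
#' the file must live on that grid, which guards against accidentally mixing
#' template spaces within a cohort.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach (`"GM"`, `"WM"`, `"PET"`).
#' @param expectedGrid optional [VolumeGrid-class] the file must match.
#' @return A [BrainVolume-class].
#' @export
readVolume <- function(path, modality = "GM", expectedGrid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- .gridFromNifti(img)
  if (!is.null(expectedGrid) && !sameGrid(grid, expectedGrid))
    stop("grid mismatch: ", path, " is not in the cohort template space")
  BrainVolume(array(as.numeric(img), dim = dim(img)[1:3]),
              grid = grid, modality = modality)
}

.gridFromNifti <- function(img) {
  d <- dim(img)
  if (length(d) < 3L) stop("malformed header: expected a 3-D volume")
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  aff <- unclass(RNifti::xform(img))
  aff <- rbind(aff[1:3, 1:4, drop = FALSE], c(0, 0, 0, 1))
  VolumeGrid(d[1:3], voxelSize = abs(pd[1:3]), affine = aff)
}

.niftiFromGrid <- function(data, grid, datatype) {
  data <- RNifti::`pixdim<-`(data, grid@voxelSize)
  img <- RNifti::asNifti(data, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(grid@affine, code = 2L))
  RNifti::`qform<-`(img, structure(grid@affine, code = 2L))
}

#' Write a volume, mask or atlas as NIfTI
#'
#' Volumes are written as float32, masks as uint8 in {0, 1}, cluster atlases
#' as int32 label volumes plus a JSON sidecar holding the cluster table.
#'
#' @param x a [BrainVolume-class], [BrainMask-class] or [ClusterAtlas-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type for plain volumes (default `"float"`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path, datatype = "float") {
  img <- .niftiFromGrid(x@data, x@grid, datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
writeMask <- function(x, path) {
  img <- .niftiFromGrid(array(as.integer(x@data), dim = dim(x@data)),
                        x@grid, "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
writeAtlas <- function(x, path) {
  img <- .niftiFromGrid(x@labels, x@grid, "int32")
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(x@clusters, sidecar, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a NIfTI mask
#'
#' Nonzero voxels become `TRUE`.
#'
#' @inheritParams readVolume
#' @return A [BrainMask-class].
#' @export
readMask <- function(path, expectedGrid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  grid <- .gridFromNifti(img)
  if (!is.null(expectedGrid) && !sameGrid(grid, expectedGrid))
    stop("grid mismatch: ", path, " is not in the cohort template space")
  BrainMask(array(as.numeric(img) != 0, dim = dim(img)[1:3]), grid = grid)
}

#' Write a feature matrix as CSV with provenance header
#'
#' Column names encode modality and cluster label (`GM_12`); the first column
#' holds subject ids.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output CSV path.
#' @export
writeFeatureMatrix <- function(fm, path) {
  vals <- fm@values
  colnames(vals) <- paste(fm@features$modality, fm@features$cluster, sep = "_")
  utils::write.csv(data.frame(subject_id = fm@subjects, vals,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
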