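#' Synthetic cohort configuration
#'
#' Study conditions for the simulated cohorts used to validate the pipeline:
#' spatially smooth tissue-density/flow maps on a shared ellipsoidal brain
#' mask, compact spherical regions whose mean intensity tracks a latent
#' cognitive trait, subject-level intracranial-volume scaling, and raw
#' neuropsychological test scores that are noisy measures of the same trait.
#'
#' Defaults mirror the analyzed long-term-memory sample: 80 subjects on a
#' 32^3 grid of 2 mm voxels, two planted regions of voxel radius 3 per
#' modality, unit effect size per latent-trait SD, and white voxel noise of
#' SD 4 smoothed at the map's intrinsic autocorrelation scale (4 mm
#' structural, 6 mm PET — about half the deliberate preprocessing filter, so
#' that after [preprocessCohort()] the total smoothness is dominated by the
#' 8/12 mm filters as in real processed maps rather than double-counted).
#' Setting a `noiseFwhm` entry to 0 keeps the noise white, which the
#' analytic correlation checks rely on.
#'
#' @param nSubjects number of subjects.
#' @param shape grid shape in voxels.
#' @param voxelSize voxel size in mm.
#' @param maskFraction ellipsoid semi-axes as a fraction of the half-shape.
#' @param nRegions planted regions per modality.
#' @param radius planted-region radius in voxels.
#' @param beta named per-modality effect size (intensity units per SD of the
#'   latent trait); scalar recycled.
#' @param baseAmplitude mean intensity of the background pattern.
#' @param noiseSD named per-modality SD of the white voxel noise before
#'   smoothing; scalar recycled.
#' @param noiseFwhm named per-modality FWHM (mm) at which the noise field is
#'   smoothed; 0 disables smoothing.
#' @param scoreNoiseSD SD of the test-level measurement noise (z-units).
#' @param icvRange range (mm^3) of the uniform intracranial-volume draw.
#' @param referenceIcv reference intracranial volume (mm^3).
#' @param batteries named list domain -> test column names, or `NULL` for
#'   [defaultBatteries()] (3/3/2/2 tests across the four domains).
#' @param seed integer seed fixing all randomness.
#' @return Config list for [generateCohort()].
#' @export
syntheticConfig <- function(nSubjects = 80L,
                            shape = c(32L, 32L, 32L),
                            voxelSize = 2,
                            maskFraction = 0.85,
                            nRegions = 2L,
                            radius = 3,
                            beta = c(GM = 1, WM = 1, PET = 1),
                            baseAmplitude = 10,
                            noiseSD = c(GM = 4, WM = 4, PET = 4),
                            noiseFwhm = c(GM = 4, WM = 4, PET = 6),
                            scoreNoiseSD = 0.5,
                            icvRange = c(1.35e6, 1.65e6),
                            referenceIcv = 1.5e6,
                            batteries = NULL,
                            seed = 1L) {
  full <- function(x) {
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, 3L), MODALITIES)
    x[MODALITIES]
  }
  cfg <- list(nSubjects = as.integer(nSubjects), shape = as.integer(shape),
              voxelSize = voxelSize, maskFraction = maskFraction,
              nRegions = as.integer(nRegions), radius = radius,
              beta = full(beta), baseAmplitude = baseAmplitude,
              noiseSD = full(noiseSD), noiseFwhm = full(noiseFwhm),
              scoreNoiseSD = scoreNoiseSD, icvRange = icvRange,
              referenceIcv = referenceIcv,
              batteries = if (is.null(batteries)) defaultBatteries() else batteries,
              seed = as.integer(seed))
  if (any(unlist(cfg$noiseSD) < 0) || cfg$scoreNoiseSD < 0)
    stop("noise SDs must be >= 0")
  if (cfg$radius < 1) stop("region radius must be >= 1 voxel")
  cfg
}

# ellipsoidal mask centred on the grid
.ellipsoidMask <- function(shape, fraction) {
  ctr <- (shape + 1) / 2
  semi <- pmax(fraction * (shape - 1) / 2, 1)
  ix <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                    z = seq_len(shape[3]))
  d <- ((ix$x - ctr[1]) / semi[1])^2 + ((ix$y - ctr[2]) / semi[2])^2 +
    ((ix$z - ctr[3]) / semi[3])^2
  array(d <= 1, dim = shape)
}

# spherical region indicator around a voxel centre
.ballIndicator <- function(shape, centre, radius) {
  ix <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                    z = seq_len(shape[3]))
  d2 <- (ix$x - centre[1])^2 + (ix$y - centre[2])^2 + (ix$z - centre[3])^2
  array(d2 <= radius^2, dim = shape)
}

# erosion of a logical volume by a ball of the given voxel radius
.erodeByBall <- function(mask, radius) {
  shape <- dim(mask)
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, , drop = FALSE]
  out <- array(TRUE, dim = shape)
  for (k in seq_len(nrow(off))) {
    sh <- array(FALSE, dim = shape)
    xs <- seq_len(shape[1]) + off$dx[k]
    ys <- seq_len(shape[2]) + off$dy[k]
    zs <- seq_len(shape[3]) + off$dz[k]
    okx <- xs >= 1 & xs <= shape[1]
    oky <- ys >= 1 & ys <= shape[2]
    okz <- zs >= 1 & zs <= shape[3]
    sh[okx, oky, okz] <- mask[xs[okx], ys[oky], zs[okz]]
    out <- out & sh
  }
  out
}

# place n disjoint balls fully inside the mask; deterministic given RNG state
.placeRegions <- function(mask, n, radius) {
  shape <- dim(mask)
  labels <- array(0L, dim = shape)
  candidates <- which(.erodeByBall(mask, radius))
  if (!length(candidates)) stop("no room for planted regions inside the mask")
  placed <- 0L
  guard <- 0L
  while (placed < n) {
    guard <- guard + 1L
    if (guard > 2000L) stop("planted regions overlap or exit the mask")
    centre <- arrayInd(candidates[sample.int(length(candidates), 1L)], shape)
    ball <- .ballIndicator(shape, centre, radius)
    if (any(labels[ball] != 0L)) next
    placed <- placed + 1L
    labels[ball] <- placed
  }
  labels
}

# fixed smooth background pattern shared by all subjects
.basePattern <- function(shape, amplitude) {
  ctr <- (shape + 1) / 2
  ix <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                    z = seq_len(shape[3]))
  d2 <- ((ix$x - ctr[1]) / shape[1])^2 + ((ix$y - ctr[2]) / shape[2])^2 +
    ((ix$z - ctr[3]) / shape[3])^2
  array(amplitude * (0.8 + 0.4 * exp(-8 * d2)), dim = shape)
}

#' Generate a synthetic multi-modal cohort
#'
#' For each subject `i` with latent trait `z_i ~ N(0, 1)`, the volume of
#' modality `m` is
#' `base + sum_r beta_m z_i 1(region_r) + noise_m`, where `noise_m` is a
#' white Gaussian field of SD `noiseSD[m]` optionally smoothed at
#' `noiseFwhm[m]`, and the whole volume is scaled by `icv_i / referenceIcv`
#' so that downstream intracranial-volume normalization is exercised. Raw
#' test scores are `a_t + b_t (z_i + eps_it)`, `eps ~ N(0, scoreNoiseSD^2)`,
#' with per-test affine display scales that composite construction absorbs.
#' All randomness is fixed by `cfg$seed`.
#'
#' @param cfg a [syntheticConfig()].
#' @return A [CohortSample-class] whose `groundTruth` holds the latent trait,
#'   per-modality region-label volumes, effect sizes and true ICVs.
#' @export
generateCohort <- function(cfg = syntheticConfig()) {
  set.seed(cfg$seed)
  n <- cfg$nSubjects
  shape <- cfg$shape
  grid <- VolumeGrid(shape, cfg$voxelSize)
  maskArr <- .ellipsoidMask(shape, cfg$maskFraction)
  mask <- BrainMask(maskArr, grid)

  z <- stats::rnorm(n)
  icv <- stats::runif(n, cfg$icvRange[1], cfg$icvRange[2])
  age <- round(stats::runif(n, 56, 86), 1)
  sex <- sample(c("M", "F"), n, replace = TRUE)

  labels <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m)
    .placeRegions(maskArr, cfg$nRegions, cfg$radius))
  beta <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m)
    rep_len(cfg$beta[[m]], cfg$nRegions))
  base <- .basePattern(shape, cfg$baseAmplitude)

  sigmaVox <- lapply(cfg$noiseFwhm, function(f)
    f / (rep_len(cfg$voxelSize, 3L) * sqrt(8 * log(2))))

  data <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m) {
    arr <- array(0, dim = c(shape, n))
    signal <- array(0, dim = shape)
    for (r in seq_len(cfg$nRegions))
      signal[labels[[m]] == r] <- beta[[m]][r]
    for (s in seq_len(n)) {
      noise <- array(stats::rnorm(prod(shape), sd = cfg$noiseSD[[m]]),
                     dim = shape)
      if (cfg$noiseFwhm[[m]] > 0) noise <- .smoothArray(noise, sigmaVox[[m]])
      arr[, , , s] <- (base + signal * z[s] + noise) * (icv[s] / cfg$referenceIcv)
    }
    arr
  })

  subjects <- sprintf("S%03d", seq_len(n))
  scores <- data.frame(subject_id = subjects, age = age, sex = sex, icv = icv,
                       stringsAsFactors = FALSE)
  tIdx <- 0L
  for (domain in names(cfg$batteries)) {
    for (test in cfg$batteries[[domain]]) {
      tIdx <- tIdx + 1L
      eps <- stats::rnorm(n, sd = cfg$scoreNoiseSD)
      scores[[test]] <- 50 + 5 * tIdx + (5 + tIdx) * (z + eps)
    }
  }

  new("CohortSample", grid = grid, mask = mask, data = data,
      subjects = subjects, scores = scores, batteries = cfg$batteries,
      groundTruth = list(z = z, labels = labels, beta = beta, icv = icv,
                         config = cfg))
}

#' Generate a null cohort (no brain-behaviour signal)
#'
#' Identical to [generateCohort()] with every effect size set to zero and
#' all noise levels matched; the ground-truth region labels are still
#' emitted. Used to calibrate the permutation comparison and to check the
#' pipeline for leakage.
#'
#' @inheritParams generateCohort
#' @return A [CohortSample-class].
#' @export
makeNullCohort <- function(cfg = syntheticConfig()) {
  cfg$beta <- stats::setNames(as.list(rep(0, 3)), MODALITIES)
  generateCohort(cfg)
}

#' Write a cohort directory
#'
#' Exports one NIfTI per subject and modality, the score table as
#' `scores.csv`, the mask, and (when present) ground-truth label volumes and
#' a `truth.json` with the latent trait, effect sizes and ICVs.
#'
#' @param cohort a [CohortSample-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMask(cohort@mask, file.path(dir, "mask.nii.gz"))
  for (m in names(cohort@data)) {
    for (s in seq_along(cohort@subjects)) {
      writeVolume(BrainVolume(cohort@data[[m]][, , , s], grid = cohort@grid,
                              modality = m),
                  file.path(dir, sprintf("%s_%s.nii.gz",
                                         cohort@subjects[s], tolower(m))))
    }
  }
  utils::write.csv(cohort@scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  gt <- cohort@groundTruth
  if (length(gt)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    for (m in names(gt$labels)) {
      img <- .niftiFromGrid(gt$labels[[m]], cohort@grid, "int32")
      RNifti::writeNifti(img, file.path(tdir, sprintf("labels_%s.nii.gz",
                                                      tolower(m))))
    }
    jsonlite::write_json(list(z = gt$z, beta = gt$beta, icv = gt$icv),
                         file.path(tdir, "truth.json"), digits = NA)
  }
  invisible(dir)
}
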