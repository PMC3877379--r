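test_that("NIfTI write/read round-trips volumes, grids and masks", {
  g <- VolumeGrid(c(12, 10, 8), voxelSize = c(2, 2, 2.5))
  set.seed(11)
  v <- BrainVolume(array(rnorm(12 * 10 * 8)^2, c(12, 10, 8)), g, "PET")
  tf <- tempfile(fileext = ".nii.gz")
  writeVolume(v, tf)
  back <- readVolume(tf, "PET")
  expect_identical(dim(volumeData(back)), c(12L, 10L, 8L))
  expect_true(sameGrid(volumeGrid(back), g))
  # float32 payloads round-trip exactly: write the already-quantized volume
  back2 <- readVolume(writeVolume(back, tf), "PET")
  expect_identical(volumeData(back2), volumeData(back))
  expect_equal(volumeData(back), volumeData(v), tolerance = 1e-6)

  m <- BrainMask(volumeData(v) > 1, g)
  tm <- tempfile(fileext = ".nii.gz")
  writeMask(m, tm)
  expect_identical(volumeData(readMask(tm)), volumeData(m))
})

test_that("grid mismatch against an expected grid is an error", {
  g <- VolumeGrid(c(8, 8, 8), 2)
  v <- BrainVolume(array(1, c(8, 8, 8)), g)
  tf <- tempfile(fileext = ".nii.gz")
  writeVolume(v, tf)
  other <- VolumeGrid(c(8, 8, 8), 3)
  expect_error(readVolume(tf, expectedGrid = other), "grid mismatch")
  expect_error(readVolume(tempfile(fileext = ".nii"), "GM"), "not found")
  expect_silent(readVolume(tf, expectedGrid = g))
})

test_that("Gaussian smoothing matches the closed-form kernel", {
  shape <- c(33, 33, 33)
  g <- VolumeGrid(shape, 2)
  a <- array(0, shape)
  a[17, 17, 17] <- 1
  s <- smoothVolume(BrainVolume(a, g, "GM"), smoothingConfig())
  sigma <- 8 / (2 * sqrt(8 * log(2)))
  expect_equal(sigma, 1.698644, tolerance = 1e-5)
  # peak of the impulse response equals the analytic 3-D Gaussian peak
  expect_equal(volumeData(s)[17, 17, 17], (2 * pi * sigma^2)^(-3 / 2),
               tolerance = 1e-4)
  # off-peak value follows the separable Gaussian profile
  expect_equal(volumeData(s)[19, 17, 17] / volumeData(s)[17, 17, 17],
               exp(-4 / (2 * sigma^2)), tolerance = 1e-4)
})

test_that("smoothing preserves mass, constants and non-negativity", {
  g <- VolumeGrid(c(14, 12, 10), 2)
  const <- smoothVolume(BrainVolume(array(3.7, c(14, 12, 10)), g, "WM"),
                        smoothingConfig())
  expect_equal(volumeData(const), array(3.7, c(14, 12, 10)),
               tolerance = 1e-6)
  set.seed(5)
  a <- array(rnorm(14 * 12 * 10)^2, c(14, 12, 10))
  s <- smoothVolume(BrainVolume(a, g, "PET"), smoothingConfig())
  expect_equal(sum(volumeData(s)), sum(a), tolerance = 1e-6)
  expect_true(all(volumeData(s) >= 0))
  expect_error(smoothVolume(BrainVolume(a, g), smoothingConfig(gm = -1)),
               "positive")
})

test_that("ICV normalization is exact linear scaling and a group action", {
  g <- VolumeGrid(c(6, 6, 6), 2)
  set.seed(7)
  v <- BrainVolume(array(rnorm(216)^2, c(6, 6, 6)), g)
  expect_equal(volumeData(icvNormalize(v, 1.5e6, 1.5e6)), volumeData(v))
  expect_equal(volumeData(icvNormalize(v, 3e6, 1.5e6)), volumeData(v) / 2)
  # normalize to an intermediate reference then on to the final one == direct
  mid <- icvNormalize(v, 1.2e6, 1.4e6)
  expect_equal(volumeData(icvNormalize(mid, 1.4e6, 1.5e6)),
               volumeData(icvNormalize(v, 1.2e6, 1.5e6)), tolerance = 1e-12)
  expect_error(icvNormalize(v, -1), "positive")
})

test_that("two subjects identical up to ICV scale agree after normalization", {
  cfg <- tiny_cohort_config(seed = 3)
  coh <- generateCohort(cfg)
  icv <- scoreTable(coh)$icv
  a1 <- volumeData(icvNormalize(
    BrainVolume(coh@data$GM[, , , 1], coh@grid), icv[1], cfg$referenceIcv))
  # rebuild subject 1's volume at subject 2's ICV from ground truth scaling
  rescaled <- coh@data$GM[, , , 1] / icv[1] * icv[2]
  a2 <- volumeData(icvNormalize(BrainVolume(rescaled, coh@grid), icv[2],
                                cfg$referenceIcv))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("block-mean downsampling matches the brute-force oracle", {
  g <- VolumeGrid(c(8, 8, 8), 2)
  v <- BrainVolume(array(rnorm(512), c(8, 8, 8)), g)
  expect_identical(downsampleVolume(v, 1L), v)
  cv <- BrainVolume(array(2.5, c(4, 4, 4)), VolumeGrid(c(4, 4, 4), 2))
  dv <- downsampleVolume(cv, 2L)
  expect_equal(volumeData(dv), array(2.5, c(2, 2, 2)))
  expect_equal(volumeGrid(dv)@voxelSize, c(4, 4, 4))

  set.seed(9)
  a <- array(rnorm(512), c(8, 8, 8))
  d <- downsampleVolume(BrainVolume(a, g), 2L)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    blk <- a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    expect_equal(volumeData(d)[i, j, k], mean(blk))
  }
  expect_equal(sum(volumeData(d)) * 2^3, sum(a) * 1, tolerance = 1e-9)

  # trailing partial blocks are averaged over present voxels
  a5 <- array(seq_len(5 * 4 * 4), c(5, 4, 4))
  d5 <- downsampleVolume(BrainVolume(a5, VolumeGrid(c(5, 4, 4), 1)), 2L)
  expect_identical(dim(volumeData(d5)), c(3L, 2L, 2L))
  expect_equal(volumeData(d5)[3, 1, 1], mean(a5[5, 1:2, 1:2]))
  expect_error(downsampleVolume(v, 0L), "positive")
})
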